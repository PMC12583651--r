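.reporting_cache <- new.env()
fit_small_posterior <- function() {
  if (is.null(.reporting_cache$post)) {
    model <- make_true_model(19, "ad_motif", seed = 5)
    cfg <- plain_config(model, sizes = c(CN = 40, EMCI = 30, LMCI = 20,
                                         AD = 20), seed = 7)
    co <- generate_cohort(cfg)$cohort
    .reporting_cache$post <- summarize_partials(
      gcgm_fit(co, iterations = 2000, burnin = 500, thin = 10, seed = 3))
  }
  .reporting_cache$post
}

test_that("network rendering is deterministic and handles empty networks", {
  post <- fit_small_posterior()
  nw <- threshold_network(post, 0.5)
  lay1 <- network_layout(nw, layout_seed = 11)
  lay2 <- network_layout(nw, layout_seed = 11)
  expect_identical(lay1, lay2)
  f <- withr::local_tempfile(fileext = ".pdf")
  render_network(nw, f, layout_seed = 11)
  expect_true(file.size(f) > 0)
  # an empty network still renders (isolated nodes)
  empty <- nw[0, , drop = FALSE]
  attr(empty, "cutoff") <- 0.5
  attr(empty, "nodes") <- post$names
  class(empty) <- class(nw)
  f2 <- withr::local_tempfile(fileext = ".pdf")
  expect_no_error(render_network(empty, f2))
  # edge width channel is affine over [cutoff, 1]
  expect_equal(bgcgm:::.edge_widths(c(0.5, 1), 0.5), c(0.5, 6))
  expect_equal(bgcgm:::.edge_widths(0.75, 0.5), mean(c(0.5, 6)))
})

test_that("subnetwork views keep only edges inside the node subset", {
  post <- fit_small_posterior()
  nw <- threshold_network(post, 0.5)
  subs <- network_subsets(post$names)
  expect_named(subs, c("age_cognition", "sex_cognition",
                       "biomarkers_cognition", "demographics_biomarkers",
                       "volume_glucose"))
  vg <- subset_network(nw, subs$volume_glucose)
  if (nrow(vg) > 0) {
    expect_true(all(grepl("^(vol|glu)_", vg$name_i)))
    expect_true(all(grepl("^(vol|glu)_", vg$name_j)))
  }
  expect_true(nrow(vg) <= nrow(nw))
})

test_that("density figures annotate mean, sd and the spike mass", {
  post <- fit_small_posterior()
  # pick the highest-probability pair so draws are present
  top <- which.max(post$prob[post$pairs])
  i <- post$pairs[top, 1]; j <- post$pairs[top, 2]
  f <- withr::local_tempfile(fileext = ".pdf")
  info <- render_density(post, i, j, f)
  expect_true(file.size(f) > 0)
  expect_equal(info$spike_mass, 1 - post$prob[i, j], tolerance = 1e-9)
  expect_equal(info$mean, post$mean_partial[i, j])
})

test_that("heatmaps share a symmetric color scale", {
  post <- fit_small_posterior()
  pz <- post$mean_partial * (post$prob >= 0.5)
  gg <- render_heatmaps(pz, pz)
  expect_s3_class(gg, "ggplot")
  lims <- ggplot2::ggplot_build(gg)$plot$scales$scales[[1]]$limits
  expect_equal(lims[1], -lims[2])
})

test_that("the pipeline writes a complete, rerunnable manifest", {
  model <- make_true_model(19, "ad_motif", seed = 5)
  gen <- plain_config(model, sizes = c(CN = 30, EMCI = 25, LMCI = 20,
                                       AD = 20), seed = 7)
  out1 <- withr::local_tempdir()
  cfgp <- pipeline_config(mode = "merged", generator = gen,
                          iterations = 1500, burnin = 400, thin = 10,
                          out_dir = out1, seed = 13, render = FALSE)
  mf <- suppressMessages(run_pipeline(cfgp))
  expect_equal(mf$p, 19)
  expect_equal(mf$n, 95)
  expect_true(all(c("cohort.csv", "truth.json", "edges.csv", "pearson.csv",
                    "sparsity.json") %in% mf$files))
  edges1 <- read.csv(file.path(out1, "edges.csv"))
  expect_equal(nrow(edges1), 19 * 18 / 2)
  # rerunning the same configuration reproduces edges.csv exactly
  out2 <- withr::local_tempdir()
  cfgp2 <- pipeline_config(mode = "merged", generator = gen,
                           iterations = 1500, burnin = 400, thin = 10,
                           out_dir = out2, seed = 13, render = FALSE)
  suppressMessages(run_pipeline(cfgp2))
  edges2 <- read.csv(file.path(out2, "edges.csv"))
  expect_identical(edges1, edges2)
  # the split-mode pipeline reports a 31-variable dictionary
  model31 <- make_true_model(31, "random", edge_density = 0.1, seed = 6)
  gen31 <- generator_config(dictionary = adni_dictionary("split"),
                            true_model = model31,
                            group_sizes = c(CN = 30, EMCI = 20, LMCI = 20,
                                            AD = 20),
                            group_mean_shift = 0,
                            group_variance_scale = c(CN = 1, EMCI = 1,
                                                     LMCI = 1, AD = 1),
                            seed = 8)
  out3 <- withr::local_tempdir()
  mf31 <- suppressMessages(run_pipeline(
    pipeline_config(mode = "split", generator = gen31, iterations = 1200,
                    burnin = 300, out_dir = out3, seed = 2, render = FALSE)))
  expect_equal(mf31$p, 31)
})

test_that("pipeline configuration is validated", {
  expect_error(pipeline_config(), "generator config or a cohort path")
  expect_error(pipeline_config(generator = list(), edge_cutoff = 1.2),
               "cutoffs")
  expect_error(pipeline_config(cohort_path = "no/such/file.csv"),
               "not found")
})
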