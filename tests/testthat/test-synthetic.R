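test_that("true models are SPD with partials in the stated band", {
  for (s in 1:5) {
    tm <- make_true_model(10, "random", edge_density = 0.25,
                          target_magnitude = 0.2, seed = s)
    expect_silent(chol(tm$precision))
    # zero pattern of K matches the graph complement
    off <- tm$precision[upper.tri(tm$precision)]
    adj <- tm$adjacency[upper.tri(tm$adjacency)]
    expect_true(all(off[adj == 0] == 0))
    expect_true(all(off[adj == 1] != 0))
    if (nrow(tm$edges) > 0) {
      band <- abs(tm$partial[as.matrix(tm$edges[, c("i", "j")])])
      expect_true(all(band >= 0.5 * 0.2 & band <= 1.5 * 0.2))
    }
    # recomputing -k_ij/sqrt(k_ii k_jj) from the stored precision agrees
    expect_equal(tm$partial, partial_from_precision(tm$precision))
  }
  empty <- make_true_model(5, "random", edge_density = 0, seed = 1)
  expect_equal(sum(empty$adjacency), 0)
  expect_equal(empty$precision, diag(5))
  full <- make_true_model(3, "random", edge_density = 1, seed = 1)
  expect_equal(sum(full$adjacency) / 2, 3)
  expect_true(all(full$partial[upper.tri(full$partial)] != 0))
})

test_that("the ad_motif structure wires the expected hub edges", {
  tm <- make_true_model(19, "ad_motif", seed = 2)
  nm <- dictionary_names(adni_dictionary("merged"))
  a <- function(x, y) tm$adjacency[match(x, nm), match(y, nm)]
  expect_equal(a("vol_hippocampus", "adni_mem"), 1L)
  expect_equal(a("vol_PCC", "adni_ef"), 1L)
  expect_equal(a("apoe4", "amyloid_stage"), 1L)
  expect_equal(a("amyloid_stage", "adni_mem"), 1L)
  expect_gt(sum(tm$adjacency[match("age", nm), ]), 3)
  expect_gt(sum(tm$adjacency[match("sex", nm), ]), 3)
})

test_that("latent sampling honors group means, scales, and the precision", {
  K <- diag(3)
  tm <- structure(list(adjacency = matrix(0L, 3, 3), precision = K,
                       partial = partial_from_precision(K),
                       edges = data.frame(i = integer(0), j = integer(0),
                                          partial = numeric(0))),
                  class = "true_model")
  dict <- adni_dictionary("merged")
  model19 <- make_true_model(19, "random", edge_density = 0.1, seed = 3)
  shifts <- matrix(0, 4, 19,
                   dimnames = list(c("CN", "EMCI", "LMCI", "AD"),
                                   dictionary_names(dict)))
  shifts["AD", "age"] <- 1.5
  cfg <- generator_config(true_model = model19,
                          group_sizes = c(CN = 4000, EMCI = 0, LMCI = 0,
                                          AD = 4000),
                          group_mean_shift = shifts,
                          group_variance_scale = c(CN = 1, EMCI = 1, LMCI = 1,
                                                   AD = 0.5),
                          seed = 6)
  lat <- sample_latent(cfg$true_model, cfg)
  cn <- lat$Z[lat$diagnosis == "CN", ]
  ad <- lat$Z[lat$diagnosis == "AD", ]
  # mean shift lands where configured (scaled SD 0.5 -> se ~ 0.008)
  expect_equal(mean(ad[, "age"]), 1.5, tolerance = 0.05)
  expect_equal(mean(cn[, "age"]), 0, tolerance = 0.07)
  # AD variance scale halves every column's SD
  expect_equal(unname(apply(ad, 2, sd) / apply(cn, 2, sd)),
               rep(0.5, 19), tolerance = 0.08)
  # law-of-large-numbers: CN columns have variance ~ diag of K^-1
  tgt <- diag(solve(model19$precision))
  expect_equal(unname(apply(cn, 2, var)), unname(tgt), tolerance = 0.1)
  # determinism
  lat2 <- sample_latent(cfg$true_model, cfg)
  expect_identical(lat$Z, lat2$Z)
})

test_that("margins are monotone, hit configured fractions, and preserve ranks", {
  model <- make_true_model(19, "random", edge_density = 0.15, seed = 9)
  cfg <- plain_config(model, sizes = c(CN = 10000, EMCI = 0, LMCI = 0, AD = 0),
                      seed = 12)
  sim <- generate_cohort(cfg)
  co <- sim$cohort
  Z <- sim$latent
  # binomial-scale check on the sex cut (expected 47%)
  expect_equal(mean(co$values$sex), 0.47, tolerance = 0.02)
  # amyloid staging yields exactly the five configured levels
  expect_setequal(unique(co$values$amyloid_stage), 0:4)
  # monotone nondecreasing in the latent, column by column
  for (k in seq_len(19)) {
    ord <- order(Z[, k])
    expect_true(all(diff(co$values[[k]][ord]) >= 0))
  }
  # monotone maps preserve Spearman correlation between columns
  s_obs <- cor(co$values$vol_hippocampus, co$values$glu_caudate,
               method = "spearman")
  s_lat <- cor(Z[, "vol_hippocampus"], Z[, "glu_caudate"],
               method = "spearman")
  expect_equal(s_obs, s_lat, tolerance = 1e-10)
  # education are integer years within [0, 25]
  expect_true(all(co$values$education == round(co$values$education)))
  expect_true(all(co$values$education >= 0 & co$values$education <= 25))
})

test_that("default cohort matches the study design; generation is reproducible", {
  cfg <- generator_config(seed = 3)
  sim <- generate_cohort(cfg)
  expect_equal(cohort_n(sim$cohort), 345 + 297 + 205 + 175)
  expect_equal(cohort_p(sim$cohort), 19)
  expect_equal(as.vector(table(sim$cohort$diagnosis)), c(345, 297, 205, 175))
  sm <- summarize_cohort(sim$cohort)
  mem <- sm$adni_mem_mean[match(c("CN", "EMCI", "LMCI", "AD"), sm$group)]
  expect_true(all(diff(mem) < 0))  # CN > EMCI > LMCI > AD ordering
  sim2 <- generate_cohort(generator_config(seed = 3))
  expect_identical(sim$cohort$values, sim2$cohort$values)
  # degenerate config: a single non-empty group
  cfg2 <- generator_config(group_sizes = c(CN = 5, EMCI = 0, LMCI = 0, AD = 0),
                           seed = 2)
  sim3 <- generate_cohort(cfg2)
  expect_equal(cohort_n(sim3$cohort), 5)
  expect_true(all(sim3$cohort$diagnosis == "CN"))
})

test_that("generator configuration is validated", {
  expect_error(make_true_model(1), "at least 2")
  expect_error(make_true_model(5, edge_density = 1.2), "edge_density")
  expect_error(generator_config(group_sizes = c(CN = -1, EMCI = 0, LMCI = 0,
                                                AD = 0)), "non-negative")
  m <- .default_margins_test <- bgcgm:::.default_margins()
  m$amyloid_stage$cut_probs <- c(0.5, 0.4, 0.7, 0.9)
  expect_error(generator_config(margins = m), "strictly increasing")
})
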