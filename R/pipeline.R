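#' Pipeline configuration
#'
#' Everything one end-to-end run needs: the dictionary mode, either a
#' generator configuration (synthetic run) or a cohort CSV path, the prior,
#' the MCMC schedule, the reporting cutoffs (edge 0.5, Pearson alpha 0.05,
#' strong 0.25), whether to add stage-stratified refits, and the output
#' directory.
#'
#' @param mode Dictionary mode, `"merged"` or `"split"`.
#' @param generator A [generator_config()], or `NULL` when loading a cohort.
#' @param cohort_path CSV path, or `NULL` when simulating.
#' @param prior A [prior_spec()].
#' @param iterations,burnin,thin MCMC schedule.
#' @param edge_cutoff,pearson_alpha,strong_cut Reporting cutoffs in (0, 1).
#' @param stratify Also fit each diagnosis group separately?
#' @param stratify_iterations,stratify_burnin Reduced schedule for the
#'   per-group refits.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param render Write figures?
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mode = c("merged", "split"), generator = NULL,
                            cohort_path = NULL, prior = prior_spec(),
                            iterations = 120000, burnin = 20000, thin = 10,
                            edge_cutoff = 0.5, pearson_alpha = 0.05,
                            strong_cut = 0.25, stratify = FALSE,
                            stratify_iterations = 20000,
                            stratify_burnin = 5000,
                            out_dir = "gcgm_results", seed = 1,
                            render = TRUE) {
  mode <- match.arg(mode)
  for (v in c(edge_cutoff, pearson_alpha, strong_cut))
    if (v <= 0 || v >= 1) stop("cutoffs must lie in (0, 1)")
  if (is.null(generator) && is.null(cohort_path))
    stop("supply either a generator config or a cohort path")
  if (!is.null(cohort_path) && !file.exists(cohort_path))
    stop("cohort file not found: ", cohort_path)
  if (iterations <= burnin) stop("iterations must exceed burnin")
  structure(list(mode = mode, generator = generator,
                 cohort_path = cohort_path, prior = prior,
                 iterations = iterations, burnin = burnin, thin = thin,
                 edge_cutoff = edge_cutoff, pearson_alpha = pearson_alpha,
                 strong_cut = strong_cut, stratify = stratify,
                 stratify_iterations = stratify_iterations,
                 stratify_burnin = stratify_burnin,
                 out_dir = out_dir, seed = as.integer(seed), render = render),
            class = "pipeline_config")
}

.log_stage <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the full analysis pipeline
#'
#' simulate/load -> transform -> fit -> summarize -> render. Writes to the
#' output directory: `cohort.csv` (synthetic runs also get `truth.json` with
#' the true edge list and partial correlations), `edges.csv` (pair,
#' probability, mean and SD of the partial correlation), `pearson.csv`,
#' `sparsity.json`, `comparison.csv` (stratified runs), figures, and
#' `manifest.json` echoing the configuration, seed, package versions, file
#' inventory and wall time — enough to rerun every seeded computation
#' identically.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly; components are also returned in the
#'   `"results"` attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(f) file.path(config$out_dir, f)
  inventory <- character(0)
  emit <- function(f) inventory <<- c(inventory, f)

  dict <- adni_dictionary(config$mode)
  if (!is.null(config$generator)) {
    .log_stage("simulate", "generating synthetic cohort")
    sim <- generate_cohort(config$generator)
    cohort <- sim$cohort
    write_cohort(cohort, outfile("cohort.csv")); emit("cohort.csv")
    truth <- list(edges = sim$model$edges,
                  partial = sim$model$partial)
    jsonlite::write_json(truth, outfile("truth.json"), digits = NA,
                         dataframe = "columns")
    emit("truth.json")
    truth_model <- sim$model
  } else {
    .log_stage("load", "reading ", config$cohort_path)
    cohort <- load_cohort(config$cohort_path, dict)
    truth_model <- NULL
  }
  if (cohort_p(cohort) != length(dict$specs))
    stop("cohort dimension does not match the ", config$mode, " dictionary")

  .log_stage("fit", "MCMC: ", config$iterations, " iterations (burn-in ",
             config$burnin, "), seed ", config$seed)
  trace <- gcgm_fit(cohort, config$prior, config$iterations, config$burnin,
                    config$thin, config$seed)
  posterior <- summarize_partials(trace)

  .log_stage("summarize", "edge tables and sparsity metrics")
  network <- threshold_network(posterior, config$edge_cutoff)
  pr <- posterior$prob[posterior$pairs]
  mp <- posterior$mean_partial[posterior$pairs]
  edges_all <- data.frame(
    i = posterior$pairs[, 1], j = posterior$pairs[, 2],
    name_i = posterior$names[posterior$pairs[, 1]],
    name_j = posterior$names[posterior$pairs[, 2]],
    prob = pr, mean_partial = mp,
    sd_partial = posterior$sd_partial[posterior$pairs])
  write.csv(edges_all, outfile("edges.csv"), row.names = FALSE)
  emit("edges.csv")
  pear <- pearson_matrix(cohort, config$pearson_alpha, config$strong_cut)
  write.csv(pear$correlation, outfile("pearson.csv")); emit("pearson.csv")
  partial_zeroed <- posterior$mean_partial *
    (posterior$prob >= config$edge_cutoff)
  sparsity <- list(
    pearson = pear$report,
    partial = sparsity_report(partial_zeroed, config$strong_cut))
  jsonlite::write_json(sparsity, outfile("sparsity.json"),
                       auto_unbox = TRUE, digits = NA)
  emit("sparsity.json")

  strat <- NULL
  if (config$stratify) {
    .log_stage("stratify", "per-stage refits")
    strat <- stratified_run(cohort, config$prior,
                            config$stratify_iterations,
                            config$stratify_burnin, config$thin,
                            config$seed, cutoff = config$edge_cutoff)
    write.csv(strat$comparison, outfile("comparison.csv"), row.names = FALSE)
    emit("comparison.csv")
  }

  if (config$render) {
    .log_stage("render", "figures")
    render_network(network, outfile("network_all.pdf"),
                   layout_seed = config$seed)
    emit("network_all.pdf")
    if (config$mode == "merged") {
      subs <- network_subsets(posterior$names)
      for (nmsub in names(subs)) {
        f <- paste0("network_", nmsub, ".pdf")
        render_network(subset_network(network, subs[[nmsub]]), outfile(f),
                       layout_seed = config$seed)
        emit(f)
      }
    }
    render_heatmaps(pear$correlation, partial_zeroed,
                    outfile("heatmaps.pdf"))
    emit("heatmaps.pdf")
    if (nrow(network) > 0) {
      top <- network[order(-network$prob), ][1, ]
      render_density(posterior, top$i, top$j, outfile("density_top_pair.pdf"))
      emit("density_top_pair.pdf")
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("bgcgm")),
    r_version = R.version.string,
    seed = config$seed,
    mode = config$mode,
    n = cohort_n(cohort), p = cohort_p(cohort),
    prior = list(edge_prob = config$prior$edge_prob, df = config$prior$df),
    mcmc = list(iterations = config$iterations, burnin = config$burnin,
                thin = config$thin),
    cutoffs = list(edge = config$edge_cutoff, alpha = config$pearson_alpha,
                   strong = config$strong_cut),
    synthetic = !is.null(config$generator),
    stratify = config$stratify,
    files = inventory,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_stage("done", "outputs in ", config$out_dir)
  attr(manifest, "results") <- list(cohort = cohort, trace = trace,
                                    posterior = posterior, network = network,
                                    pearson = pear, sparsity = sparsity,
                                    stratified = strat, truth = truth_model)
  invisible(manifest)
}
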