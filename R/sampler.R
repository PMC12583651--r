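#' Trans-dimensional MCMC over graphs and precision matrices
#'
#' Samples from the joint posterior P(G, K | Z) proportional to
#' P(Z | K) P(K, G): a Bernoulli prior over edges, a G-Wishart prior on the
#' precision given the graph, and a latent-Gaussian likelihood. Each
#' iteration (i) resamples the discrete latent columns under the current
#' precision (extended rank likelihood), (ii) performs one single-edge
#' birth/death Metropolis-Hastings move using a partial-analytic conditional
#' with an exchange (auxiliary G-Wishart prior draw) step, so that no
#' G-Wishart normalizing constants are ever evaluated, and (iii) refreshes
#' the precision from its conditional posterior GW(df + n, scale + Z'Z)
#' restricted to the graph. Fully reproducible given `seed`.
#'
#' `mcmc_run` is the low-level entry taking a prepared latent matrix;
#' [gcgm_fit()] is the user-facing wrapper that also performs the initial
#' semiparametric transform.
#'
#' @param Z0 A [init_latent()] result, or a plain numeric matrix (all columns
#'   then treated as continuous and used as-is). Zero rows are allowed, in
#'   which case the chain targets the prior.
#' @param observed The matching [cohort_table()]; `NULL` when `Z0` has no
#'   discrete columns.
#' @param prior A [prior_spec()].
#' @param iterations,burnin Total and discarded iterations.
#' @param thin Keep every `thin`-th post-burn-in sample in the stores.
#' @param seed Integer seed.
#' @param start_adjacency Optional starting graph (default empty).
#' @param p Number of variables; only needed when `Z0` has zero rows.
#' @return An object of class `"gcgm_trace"`: stored adjacency and
#'   partial-correlation draws (pair-by-sample matrices), unit sample
#'   weights, edge-count trace, acceptance rate, first/second-half edge
#'   frequencies, and the run configuration.
#' @export
mcmc_run <- function(Z0, observed = NULL, prior = prior_spec(),
                     iterations = 120000, burnin = 20000, thin = 10,
                     seed = 1, start_adjacency = NULL, p = NULL) {
  if (iterations <= burnin) stop("iterations must exceed burnin")
  if (thin < 1) stop("thin must be >= 1")
  if (inherits(Z0, "latent_matrix")) {
    Z <- Z0$Z
    disc <- which(Z0$discrete)
    vnames <- Z0$names
  } else {
    Z <- as.matrix(Z0)
    disc <- integer(0)
    vnames <- colnames(Z)
  }
  if (is.null(dim(Z)) || (nrow(Z) == 0 && is.null(ncol(Z))))
    stop("Z0 must be a matrix or latent_matrix")
  if (nrow(Z) == 0) {
    if (!is.null(p) && ncol(Z) == 0) Z <- matrix(0, 0, p)
    if (ncol(Z) == 0) stop("supply p for an empty data matrix")
  }
  p <- ncol(Z)
  if (is.null(vnames)) vnames <- paste0("V", seq_len(p))
  if (length(disc) > 0) {
    if (is.null(observed)) stop("observed cohort required for discrete columns")
    Yd <- cohort_values_matrix(observed)[, disc, drop = FALSE]
    storage.mode(Yd) <- "integer"
  } else {
    Yd <- matrix(0L, nrow(Z), 0)
  }
  adj <- if (is.null(start_adjacency)) matrix(0L, p, p) else start_adjacency
  .check_adj(adj)
  D <- .prior_scale(prior, p)
  set.seed(seed)
  res <- gcgm_mcmc_cpp(Z, Yd, as.integer(disc - 1), adj == 1,
                       prior$df, D, prior$edge_prob,
                       as.integer(iterations), as.integer(burnin),
                       as.integer(thin), 1e-8, 100)
  pairs <- t(res$pairs) + 1L
  colnames(pairs) <- c("i", "j")
  structure(list(
    adj_samples = res$adj_samples, partial_samples = res$partial_samples,
    weights = rep(1, res$nstored), edge_count = as.integer(res$edge_count),
    pairs = pairs, p = p, names = vnames,
    edge_freq = res$edge_freq, half1 = res$half1, half2 = res$half2,
    accept_rate = res$accept_rate, n = nrow(Z),
    iterations = iterations, burnin = burnin, thin = thin, seed = seed,
    prior = prior), class = "gcgm_trace")
}

#' @export
print.gcgm_trace <- function(x, ...) {
  cat("GCGM posterior trace: p =", x$p, ", n =", x$n, "\n")
  cat("  iterations =", x$iterations, "(burn-in", x$burnin,
      ", thin", x$thin, "), stored samples =", length(x$weights), "\n")
  cat("  edge-move acceptance rate =", round(x$accept_rate, 3), "\n")
  invisible(x)
}

#' Fit a Gaussian copula graphical model to a cohort
#'
#' Transforms the cohort to the latent scale ([init_latent()]) and runs the
#' trans-dimensional sampler ([mcmc_run()]).
#'
#' @param cohort A [cohort_table()].
#' @param prior A [prior_spec()].
#' @param iterations,burnin,thin,seed Passed to [mcmc_run()].
#' @param transform Semiparametric transform variant ([nonparanormal()]).
#' @return A `"gcgm_trace"`.
#' @export
gcgm_fit <- function(cohort, prior = prior_spec(), iterations = 120000,
                     burnin = 20000, thin = 10, seed = 1,
                     transform = c("rank", "winsorized")) {
  lat <- init_latent(cohort, match.arg(transform))
  mcmc_run(lat, cohort, prior, iterations, burnin, thin, seed)
}

## all 2^M graphs on p nodes, as a list of adjacency matrices
.all_graphs <- function(p) {
  M <- p * (p - 1) / 2
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  lapply(seq_len(2^M) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(M)]
    adj <- matrix(0L, p, p)
    for (e in seq_len(M)) {
      adj[pairs[e, 1], pairs[e, 2]] <- bits[e]
      adj[pairs[e, 2], pairs[e, 1]] <- bits[e]
    }
    adj
  })
}

#' Exact posterior over graphs by enumeration (p <= 3)
#'
#' For up to three all-continuous variables every graph is decomposable, so
#' the G-Wishart normalizing constant factorizes over cliques and separators
#' in closed form and the graph posterior
#' P(G | Z) proportional to P(G) I_G(df + n, scale + Z'Z) / I_G(df, scale)
#' can be evaluated exactly for all graphs. Serves as the independent oracle
#' for the trans-dimensional sampler.
#'
#' @param Z n x p latent (continuous) data matrix, n >= 0, p <= 3.
#' @param prior A [prior_spec()].
#' @return List with `edge_prob` (p x p exact edge-inclusion probabilities),
#'   `graphs` (data.frame of graph codes, edge counts and posterior
#'   probabilities) and `log_marginals`.
#' @export
enumerate_posterior <- function(Z, prior = prior_spec()) {
  Z <- as.matrix(Z)
  p <- ncol(Z)
  if (p > 3) stop("enumeration supported only for p <= 3 ",
                  "(non-decomposable graphs appear at p = 4)")
  n <- nrow(Z)
  D <- .prior_scale(prior, p)
  Dstar <- D + if (n > 0) crossprod(Z) else 0
  graphs <- .all_graphs(p)
  M <- p * (p - 1) / 2
  logw <- vapply(graphs, function(adj) {
    ne <- sum(adj) / 2
    ne * log(prior$edge_prob) + (M - ne) * log(1 - prior$edge_prob) +
      .log_gwishart_norm(adj, prior$df + n, Dstar) -
      .log_gwishart_norm(adj, prior$df, D)
  }, 0)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  ep <- matrix(0, p, p)
  for (g in seq_along(graphs)) ep <- ep + w[g] * graphs[[g]]
  dimnames(ep) <- list(colnames(Z), colnames(Z))
  list(edge_prob = ep,
       graphs = data.frame(code = seq_along(graphs) - 1L,
                           n_edges = vapply(graphs, function(a) sum(a) / 2, 0),
                           prob = w),
       log_marginals = logw)
}

#' Convergence diagnostics for a trace
#'
#' Compares edge-inclusion probabilities between the first and second half of
#' the post-burn-in run (and across two independently seeded chains when a
#' second trace is supplied) and summarizes the edge-count trace. The run is
#' flagged as not converged when any absolute edge-probability difference
#' exceeds `threshold`.
#'
#' @param trace A `"gcgm_trace"`.
#' @param second_trace Optional second chain over the same variables.
#' @param threshold Flagging threshold on edge-probability differences.
#' @return An object of class `"gcgm_convergence"`.
#' @export
convergence_check <- function(trace, second_trace = NULL, threshold = 0.05) {
  if (length(trace$weights) == 0) stop("empty trace")
  half_diff <- max(abs(trace$half1 - trace$half2))
  ec <- trace$edge_count
  cross <- NA_real_
  if (!is.null(second_trace)) {
    if (second_trace$p != trace$p) stop("traces have different dimensions")
    cross <- max(abs(edge_probabilities(trace) -
                     edge_probabilities(second_trace)))
  }
  converged <- half_diff <= threshold && (is.na(cross) || cross <= threshold)
  structure(list(half_diff = half_diff, cross_diff = cross,
                 edge_count = summary(ec), threshold = threshold,
                 converged = converged),
            class = "gcgm_convergence")
}

#' @export
print.gcgm_convergence <- function(x, ...) {
  cat("First/second-half max |edge prob diff|:", signif(x$half_diff, 3), "\n")
  if (!is.na(x$cross_diff))
    cat("Cross-chain max |edge prob diff|:", signif(x$cross_diff, 3), "\n")
  cat("Edge count: "); print(x$edge_count)
  cat(if (x$converged) "No convergence problems flagged"
      else paste0("NOT CONVERGED (threshold ", x$threshold, ")"), "\n")
  invisible(x)
}
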