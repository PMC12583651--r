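#' Partial correlations from a precision matrix
#'
#' `rho_ij = -k_ij / sqrt(k_ii k_jj)`; the diagonal is reported as zero by
#' convention, and entries are exactly zero wherever `k_ij = 0`. Equals the
#' conditional correlation of each pair given all remaining variables.
#'
#' @param K SPD precision matrix.
#' @return Symmetric matrix of partial correlations, zero diagonal.
#' @export
partial_from_precision <- function(K) {
  .check_spd(K, "K")
  d <- sqrt(diag(K))
  P <- -K / outer(d, d)
  diag(P) <- 0
  P
}

.pair_matrix <- function(trace, values) {
  P <- matrix(0, trace$p, trace$p, dimnames = list(trace$names, trace$names))
  P[trace$pairs] <- values
  P + t(P)
}

#' Posterior edge-inclusion probabilities
#'
#' Weight-normalized frequency of edge presence across the stored samples:
#' if 30% of the sampled graphs contain an edge, the probability of
#' conditional dependence for that pair is 0.30.
#'
#' @param trace A `"gcgm_trace"`.
#' @return Symmetric p x p matrix of probabilities in \[0, 1\].
#' @export
edge_probabilities <- function(trace) {
  if (length(trace$weights) == 0) stop("empty trace")
  w <- trace$weights / sum(trace$weights)
  .pair_matrix(trace, as.numeric(trace$adj_samples %*% w))
}

#' Model-averaged partial correlations with uncertainty
#'
#' Per pair, the mean and standard deviation of the partial correlation over
#' all stored draws, with absent-edge draws contributing exactly zero (this
#' is what produces the spike at zero in posterior density plots: the spike
#' mass equals one minus the edge-inclusion probability). The full draw
#' store is retained for density plots and interval queries.
#'
#' @param trace A `"gcgm_trace"`.
#' @return An object of class `"edge_posterior"`: `prob`, `mean_partial`,
#'   `sd_partial` matrices plus the per-pair sample store.
#' @export
summarize_partials <- function(trace) {
  if (length(trace$weights) == 0) stop("empty trace")
  w <- trace$weights / sum(trace$weights)
  m <- as.numeric(trace$partial_samples %*% w)
  m2 <- as.numeric((trace$partial_samples^2) %*% w)
  structure(list(
    prob = edge_probabilities(trace),
    mean_partial = .pair_matrix(trace, m),
    sd_partial = .pair_matrix(trace, sqrt(pmax(m2 - m^2, 0))),
    samples = trace$partial_samples, adj_samples = trace$adj_samples,
    weights = trace$weights, pairs = trace$pairs, p = trace$p,
    names = trace$names), class = "edge_posterior")
}

#' @export
print.edge_posterior <- function(x, ...) {
  cat("Edge posterior over", x$p, "variables;",
      sum(x$prob[upper.tri(x$prob)] >= 0.5), "of", nrow(x$pairs),
      "pairs at probability >= 0.5\n")
  invisible(x)
}

.pair_row <- function(posterior, i, j) {
  which(posterior$pairs[, 1] == min(i, j) & posterior$pairs[, 2] == max(i, j))
}

#' Posterior probability that a partial correlation lies in an interval
#'
#' Weighted fraction of stored draws in `[a, b]`; the spike at zero (absent
#' edge draws) is included exactly when `a <= 0 <= b`. Supports statements
#' such as "the partial correlation lies between 0.1 and 0.2 with 90%
#' probability".
#'
#' @param posterior An [summarize_partials()] result.
#' @param i,j Variable indices (or names).
#' @param a,b Interval endpoints, `a <= b`.
#' @return Probability in \[0, 1\].
#' @export
interval_probability <- function(posterior, i, j, a, b) {
  if (a > b) stop("a must not exceed b")
  if (is.character(i)) i <- match(i, posterior$names)
  if (is.character(j)) j <- match(j, posterior$names)
  r <- .pair_row(posterior, i, j)
  draws <- posterior$samples[r, ]
  w <- posterior$weights / sum(posterior$weights)
  inside <- draws >= a & draws <= b
  # absent-edge draws are stored as exact zeros; drop them if 0 is outside [a,b]
  if (!(a <= 0 && 0 <= b))
    inside <- inside & posterior$adj_samples[r, ] == 1
  sum(w[inside])
}

#' Median-probability-style thresholded network
#'
#' Keeps the pairs whose edge-inclusion probability reaches `cutoff`
#' (default 0.5, the median probability model). Each reported edge carries
#' its probability (figure width channel), model-averaged partial
#' correlation (magnitude) and sign (color channel).
#'
#' @param posterior An [summarize_partials()] result.
#' @param cutoff Probability threshold in (0, 1).
#' @return Data.frame of class `"gcgm_network"` with columns `i`, `j`,
#'   `name_i`, `name_j`, `prob`, `mean_partial`, `sd_partial`, `sign`.
#' @export
threshold_network <- function(posterior, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  pr <- posterior$prob[posterior$pairs]
  keep <- which(pr >= cutoff)
  mp <- posterior$mean_partial[posterior$pairs]
  sdp <- posterior$sd_partial[posterior$pairs]
  out <- data.frame(
    i = posterior$pairs[keep, 1], j = posterior$pairs[keep, 2],
    name_i = posterior$names[posterior$pairs[keep, 1]],
    name_j = posterior$names[posterior$pairs[keep, 2]],
    prob = pr[keep], mean_partial = mp[keep], sd_partial = sdp[keep],
    sign = ifelse(mp[keep] >= 0, "positive", "negative"))
  attr(out, "cutoff") <- cutoff
  attr(out, "p") <- posterior$p
  attr(out, "nodes") <- posterior$names
  class(out) <- c("gcgm_network", "data.frame")
  out
}

#' Pearson-correlation baseline with significance zeroing
#'
#' Product-moment correlations on the raw observed codings, with each pair's
#' two-sided t-test p-value; entries with `p > alpha` are set to zero. This
#' is the naive marginal baseline the partial-correlation network is
#' contrasted with. Constant columns yield undefined correlations, reported
#' as zero with a warning.
#'
#' @param cohort A [cohort_table()].
#' @param alpha Significance level for zeroing (default 0.05).
#' @param strong_cut Threshold for the "strong correlation" tally.
#' @return List with `correlation` (zeroed), `raw`, `pvalue` and `report`
#'   (a [sparsity_report()]; `avg_abs` is computed before zeroing).
#' @export
pearson_matrix <- function(cohort, alpha = 0.05, strong_cut = 0.25) {
  X <- cohort_values_matrix(cohort)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 rows")
  p <- ncol(X)
  const <- apply(X, 2, function(x) max(x) == min(x))
  if (any(const))
    warning("constant column(s): ", paste(colnames(X)[const], collapse = ", "),
            "; their correlations are reported as 0")
  R <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  P <- matrix(1, p, p, dimnames = dimnames(R))
  diag(R) <- 1; diag(P) <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (const[i] || const[j]) next
    ct <- cor.test(X[, i], X[, j])
    R[i, j] <- R[j, i] <- unname(ct$estimate)
    P[i, j] <- P[j, i] <- ct$p.value
  }
  zeroed <- R
  zeroed[P > alpha] <- 0
  diag(zeroed) <- 1
  rep_zeroed <- sparsity_report(zeroed, strong_cut)
  rep_raw <- sparsity_report(R, strong_cut)
  report <- list(avg_abs = rep_raw$avg_abs, frac_zero = rep_zeroed$frac_zero,
                 frac_strong = rep_zeroed$frac_strong,
                 strong_cut = strong_cut)
  list(correlation = zeroed, raw = R, pvalue = P, report = report)
}

#' Sparsity metrics of a (zero-ruled) association matrix
#'
#' Over unordered off-diagonal pairs: the mean absolute value, the fraction
#' of exact zeros, and the fraction of "strong" entries with absolute value
#' above `strong_cut` (default 0.25).
#'
#' @param matrix Symmetric association matrix.
#' @param strong_cut Strong-association threshold.
#' @return List with `avg_abs`, `frac_zero`, `frac_strong`, `strong_cut`.
#' @export
sparsity_report <- function(matrix, strong_cut = 0.25) {
  v <- matrix[upper.tri(matrix)]
  list(avg_abs = mean(abs(v)), frac_zero = mean(v == 0),
       frac_strong = mean(abs(v) > strong_cut), strong_cut = strong_cut)
}

#' Stage-stratified refits
#'
#' Runs the full transform-and-fit pipeline on the pooled cohort and on each
#' diagnosis group separately (groups below `min_n` rows are skipped with a
#' warning), then tabulates per run the fraction of pairs below the edge
#' cutoff and the average absolute model-averaged partial correlation (both
#' over all pairs, and over retained pairs only).
#'
#' @param cohort A [cohort_table()].
#' @param prior A [prior_spec()].
#' @param iterations,burnin,thin,seed MCMC settings (group g uses
#'   `seed + g`).
#' @param min_n Minimum group size; smaller groups are skipped.
#' @param cutoff Edge-probability cutoff for the comparison table.
#' @return List with `pooled` (an `edge_posterior`), `groups` (named list of
#'   `edge_posterior`), and `comparison` (data.frame).
#' @export
stratified_run <- function(cohort, prior = prior_spec(), iterations = 20000,
                           burnin = 5000, thin = 10, seed = 1, min_n = 30,
                           cutoff = 0.5) {
  sizes <- table(cohort$diagnosis)
  if (all(sizes == 0)) stop("all diagnosis groups are empty")
  pooled <- summarize_partials(
    gcgm_fit(cohort, prior, iterations, burnin, thin, seed))
  groups <- list()
  g_i <- 0
  for (g in levels(cohort$diagnosis)) {
    g_i <- g_i + 1
    if (sizes[[g]] < min_n) {
      warning("group ", g, " has ", sizes[[g]], " rows (< ", min_n,
              "); skipped")
      next
    }
    sub <- cohort_subset(cohort, cohort$diagnosis == g)
    groups[[g]] <- summarize_partials(
      gcgm_fit(sub, prior, iterations, burnin, thin, seed + g_i))
  }
  row_of <- function(name, post, n) {
    pr <- post$prob[post$pairs]
    mp <- post$mean_partial[post$pairs]
    kept <- pr >= cutoff
    data.frame(run = name, n = n,
               frac_below_cutoff = mean(!kept),
               avg_abs_partial = mean(abs(ifelse(kept, mp, 0))),
               avg_abs_partial_retained =
                 if (any(kept)) mean(abs(mp[kept])) else 0)
  }
  comparison <- rbind(
    row_of("pooled", pooled, cohort_n(cohort)),
    do.call(rbind, lapply(names(groups), function(g)
      row_of(g, groups[[g]], sizes[[g]]))))
  rownames(comparison) <- NULL
  list(pooled = pooled, groups = groups, comparison = comparison)
}
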