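#' Rank-based semiparametric (nonparanormal) transform
#'
#' Maps a continuous column to the latent Gaussian scale through its ranks:
#' `z_i = qnorm(r_i / (n + 1))` with average ranks for ties. The `n + 1`
#' denominator bounds the transform away from +/-Inf, which is the property
#' the usual Winsorized estimator exists for; that variant (truncation of the
#' empirical CDF at `1 / (4 n^{1/4} sqrt(pi log n))`) is available as
#' `method = "winsorized"`. The output is invariant to strictly increasing
#' transformations of the input.
#'
#' @param y Numeric vector, length >= 3, not constant.
#' @param method `"rank"` (default) or `"winsorized"`.
#' @return Numeric vector of latent values.
#' @export
nonparanormal <- function(y, method = c("rank", "winsorized")) {
  method <- match.arg(method)
  n <- length(y)
  if (n < 3) stop("nonparanormal transform needs at least 3 observations")
  if (anyNA(y)) stop("missing values in input")
  if (max(y) == min(y)) stop("transform undefined for a constant column")
  if (method == "rank") {
    qnorm(rank(y, ties.method = "average") / (n + 1))
  } else {
    dn <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
    u <- rank(y, ties.method = "average") / n
    qnorm(pmin(pmax(u, dn), 1 - dn))
  }
}

#' Initial latent matrix for a cohort
#'
#' Continuous columns (including age) are transformed once with the
#' semiparametric transform and standardized to unit variance; they stay
#' frozen for the whole chain. Discrete columns (sex, education, APOE4,
#' amyloid stage) get rank-based starting values and are resampled at every
#' MCMC iteration under the extended rank likelihood.
#'
#' @param cohort A [cohort_table()].
#' @param method Transform variant passed to [nonparanormal()].
#' @return An object of class `"latent_matrix"`: list with `Z` (n x p),
#'   `discrete` (logical mask) and `names`.
#' @export
init_latent <- function(cohort, method = c("rank", "winsorized")) {
  method <- match.arg(method)
  mask <- discrete_mask(cohort$dictionary)
  n <- cohort_n(cohort)
  Z <- matrix(0, n, cohort_p(cohort),
              dimnames = list(NULL, dictionary_names(cohort$dictionary)))
  for (k in seq_len(ncol(Z))) {
    y <- cohort$values[[k]]
    if (mask[k]) {
      # rank starting values; ties share a latent value, which satisfies the
      # (strict-on-strict) rank-consistency invariant
      Z[, k] <- qnorm(rank(y, ties.method = "average") / (n + 1))
    } else {
      z <- nonparanormal(y, method)
      Z[, k] <- z / sd(z)
    }
  }
  structure(list(Z = Z, discrete = mask, names = colnames(Z)),
            class = "latent_matrix")
}

#' Extended-rank-likelihood truncation bounds for one cell
#'
#' For a discrete column the latent value of row `row` is constrained only by
#' the ordering of the observed values: the lower bound is the largest latent
#' value among rows with a strictly smaller observation (-Inf if none), the
#' upper bound the smallest latent value among rows with a strictly larger
#' observation (+Inf if none). Ties impose no mutual constraint.
#'
#' @param observed_column Observed (coded) values.
#' @param latent_column Current latent values.
#' @param row Row index.
#' @return Numeric `c(lower, upper)`.
#' @export
rank_bounds <- function(observed_column, latent_column, row) {
  y <- observed_column[row]
  below <- latent_column[observed_column < y]
  above <- latent_column[observed_column > y]
  c(if (length(below)) max(below) else -Inf,
    if (length(above)) min(above) else Inf)
}

#' One Gibbs sweep over the discrete latent columns
#'
#' For each discrete column (fixed column-major order) and each row, the
#' latent value is redrawn from the univariate normal with mean
#' `-(1/k_jj) * sum_{l != j} k_jl z_il` and variance `1/k_jj` — the exact
#' conditional of N(0, K^-1) — truncated to its [rank_bounds()]. Continuous
#' columns are untouched. Randomness comes from R's RNG stream.
#'
#' @param latent A [init_latent()] result.
#' @param observed The matching [cohort_table()].
#' @param K Symmetric positive-definite p x p precision matrix.
#' @return The updated `latent_matrix`.
#' @export
resample_discrete_latents <- function(latent, observed, K) {
  p <- ncol(latent$Z)
  stopifnot(nrow(K) == p, ncol(K) == p)
  if (inherits(try(chol(K), silent = TRUE), "try-error"))
    stop("K must be symmetric positive definite")
  idx <- which(latent$discrete)
  if (length(idx) == 0) return(latent)
  Yd <- as.matrix(cohort_values_matrix(observed)[, idx, drop = FALSE])
  storage.mode(Yd) <- "integer"
  dn <- dimnames(latent$Z)
  latent$Z <- copula_sweep_cpp(latent$Z, Yd, as.integer(idx - 1), K)
  dimnames(latent$Z) <- dn
  latent
}

#' Observed values as a numeric matrix (dictionary order)
#' @param cohort A [cohort_table()].
#' @return Numeric n x p matrix.
#' @export
cohort_values_matrix <- function(cohort) {
  as.matrix(cohort$values)
}

#' Exact conditional of one latent coordinate under N(0, K^-1)
#'
#' The precision-parameterized conditional used by the discrete updates:
#' mean `-(1/k_jj) * sum_{l != j} k_jl z_l`, variance `1/k_jj`. Equals the
#' Schur-complement conditional computed from the covariance.
#'
#' @param K Precision matrix.
#' @param j Coordinate index.
#' @param z Current latent vector (entry `j` ignored).
#' @return List with `mean` and `var`.
#' @export
conditional_normal <- function(K, j, z) {
  kjj <- K[j, j]
  list(mean = -(sum(K[j, ] * z) - kjj * z[j]) / kjj, var = 1 / kjj)
}
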