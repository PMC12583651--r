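# Shared fixtures, built in code at test time.

# random SPD matrix with moderate conditioning
random_spd <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(p * p), p, p)
  crossprod(A) / p + diag(p)
}

# latent Gaussian draws from a given precision matrix
latent_draws <- function(n, K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(K)
  matrix(rnorm(n * p), n, p) %*% chol(solve(K))
}

# a tiny valid merged-mode cohort (hand-built, deterministic)
tiny_cohort <- function(n = 8) {
  set.seed(99)
  dict <- adni_dictionary("merged")
  vals <- data.frame(
    age = round(seq(62, 85, length.out = n), 1),
    sex = rep(c(0L, 1L), length.out = n),
    education = rep(c(12L, 16L, 18L, 20L), length.out = n),
    adni_mem = round(seq(-2, 2, length.out = n), 2),
    adni_ef = round(seq(-1.5, 2.5, length.out = n), 2),
    apoe4 = rep(c(1L, 0L), length.out = n),
    amyloid_stage = rep(0:3, length.out = n))
  for (nm in dictionary_names(dict)[8:19])
    vals[[nm]] <- round(runif(n, 1, 8), 3)
  cohort_table(vals, rep(c("CN", "EMCI", "LMCI", "AD"), length.out = n), dict)
}

# small generator config with homogeneous groups (pure latent law)
plain_config <- function(true_model, sizes = c(CN = 60, EMCI = 50,
                                               LMCI = 45, AD = 45),
                         seed = 4, gaussian_margins = FALSE) {
  generator_config(true_model = true_model, group_sizes = sizes,
                   group_mean_shift = 0,
                   group_variance_scale = c(CN = 1, EMCI = 1, LMCI = 1, AD = 1),
                   gaussian_margins = gaussian_margins, seed = seed)
}

# brute-force partial correlation of (i, j) given the rest, from Sigma
partial_by_conditioning <- function(K, i, j) {
  Sigma <- solve(K)
  rest <- setdiff(seq_len(nrow(K)), c(i, j))
  if (length(rest) == 0) {
    C <- Sigma
  } else {
    C <- Sigma[c(i, j), c(i, j)] -
      Sigma[c(i, j), rest, drop = FALSE] %*%
        solve(Sigma[rest, rest, drop = FALSE],
              Sigma[rest, c(i, j), drop = FALSE])
  }
  C[1, 2] / sqrt(C[1, 1] * C[2, 2])
}
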