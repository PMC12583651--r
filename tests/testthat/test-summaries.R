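test_that("partial correlations equal brute-force conditional correlations", {
  # identity and a hand-checked tridiagonal case
  expect_equal(partial_from_precision(diag(4)), matrix(0, 4, 4))
  K <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3, 3)
  P <- partial_from_precision(K)
  expect_equal(P[1, 2], -0.5)
  expect_equal(P[1, 3], 0)
  expect_equal(P[2, 3], -0.5)
  K2 <- matrix(c(1, -0.5, -0.5, 1), 2, 2)
  expect_equal(partial_from_precision(K2)[1, 2], 0.5)
  # 100 random SPD matrices up to p = 6, elementwise 1e-10 against the
  # Schur-complement conditional-correlation route
  for (s in 1:100) {
    p <- 2 + (s %% 5)
    K <- random_spd(p, seed = 700 + s)
    P <- partial_from_precision(K)
    i <- 1 + (s %% (p - 1)); j <- p
    expect_equal(P[i, j], partial_by_conditioning(K, i, j), tolerance = 1e-10)
  }
  expect_error(partial_from_precision(matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

make_toy_trace <- function(adj_samples, partial_samples, weights = NULL,
                           p = 3) {
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 2], pairs[, 1]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  structure(list(adj_samples = adj_samples, partial_samples = partial_samples,
                 weights = if (is.null(weights)) rep(1, ncol(adj_samples))
                           else weights,
                 edge_count = colSums(adj_samples), pairs = pairs, p = p,
                 names = paste0("V", 1:p)), class = "gcgm_trace")
}

test_that("edge probabilities are weight-normalized sample frequencies", {
  # 10 unit-weight samples with the (1,2) edge in 3 -> probability 0.30
  A <- matrix(0, 3, 10); A[1, 1:3] <- 1
  P <- A * 0.5
  tr <- make_toy_trace(A, P)
  ep <- edge_probabilities(tr)
  expect_equal(ep[1, 2], 0.3)
  expect_equal(ep[1, 3], 0)
  # saturation
  A2 <- matrix(1, 3, 10)
  expect_true(all(edge_probabilities(make_toy_trace(A2, A2 * 0.1))[
    upper.tri(diag(3))] == 1))
  # waiting-time style weights (2,1,1), edge only in the first sample
  A3 <- matrix(0, 3, 3); A3[1, 1] <- 1
  tr3 <- make_toy_trace(A3, A3 * 0.2, weights = c(2, 1, 1))
  expect_equal(edge_probabilities(tr3)[1, 2], 0.5)
})

test_that("model-averaged partials treat absent edges as exact zeros", {
  # always absent: mean 0, sd 0, spike mass 1
  A <- matrix(0, 3, 8)
  post <- summarize_partials(make_toy_trace(A, A))
  expect_equal(post$mean_partial[1, 2], 0)
  expect_equal(post$sd_partial[1, 2], 0)
  expect_equal(interval_probability(post, 1, 2, -1, 1), 1)
  expect_equal(interval_probability(post, 1, 2, 0.1, 0.4), 0)
  # always present at constant rho: mean rho, sd 0
  A2 <- matrix(0, 3, 8); A2[2, ] <- 1
  P2 <- A2 * 0.25
  post2 <- summarize_partials(make_toy_trace(A2, P2))
  expect_equal(post2$mean_partial[1, 3], 0.25)
  expect_equal(post2$sd_partial[1, 3], 0)
  # mixed: spike mass equals 1 - edge probability
  A3 <- matrix(0, 3, 10); A3[3, 1:4] <- 1
  P3 <- A3 * 0.4
  post3 <- summarize_partials(make_toy_trace(A3, P3))
  expect_equal(post3$prob[2, 3], 0.4)
  expect_equal(interval_probability(post3, 2, 3, -0.01, 0.01), 0.6)
  expect_equal(post3$mean_partial[2, 3], 0.16)
})

test_that("interval probabilities are additive over partitions", {
  set.seed(26)
  A <- matrix(rbinom(3 * 50, 1, 0.6), 3, 50)
  P <- A * matrix(runif(150, -0.9, 0.9), 3, 50)
  post <- summarize_partials(make_toy_trace(A, P))
  cuts <- c(-1, -0.3, 0, 0.24, 1)
  tot <- interval_probability(post, 1, 2, -1, cuts[2] - 1e-12) +
    interval_probability(post, 1, 2, cuts[2], -1e-12) +
    interval_probability(post, 1, 2, 0, cuts[4] - 1e-12) +
    interval_probability(post, 1, 2, cuts[4], 1)
  expect_equal(tot, 1, tolerance = 1e-9)
  expect_error(interval_probability(post, 1, 2, 0.5, 0.1), "must not exceed")
})

test_that("thresholded networks shrink monotonically in the cutoff", {
  set.seed(27)
  A <- matrix(rbinom(3 * 40, 1, 0.5), 3, 40)
  P <- A * 0.3
  post <- summarize_partials(make_toy_trace(A, P))
  prev <- Inf
  for (cut in c(0.5, 0.6, 0.7, 0.8, 0.9)) {
    nw <- threshold_network(post, cut)
    expect_lte(nrow(nw), prev)
    prev <- nrow(nw)
    if (nrow(nw) > 0) expect_true(all(nw$prob >= cut))
  }
  # sub-threshold matrix gives an empty network; a strong negative edge is red
  A2 <- matrix(0, 3, 10); A2[1, 1:9] <- 1
  P2 <- A2 * -0.2
  post2 <- summarize_partials(make_toy_trace(A2, P2))
  nw2 <- threshold_network(post2, 0.5)
  expect_equal(nrow(nw2), 1)
  expect_equal(nw2$sign, "negative")
  expect_equal(nw2$prob, 0.9)
})

test_that("Pearson baseline zeroes insignificant pairs and tallies sparsity", {
  set.seed(28)
  n <- 1000
  x <- rnorm(n); y <- 0.6 * x + rnorm(n) * sqrt(1 - 0.36)
  co <- tiny_cohort(8)  # only for the dictionary scaffold
  # direct checks on a raw matrix via cor.test semantics
  dict <- co$dictionary
  vals <- as.data.frame(matrix(rnorm(n * 19), n, 19))
  names(vals) <- dictionary_names(dict)
  vals$sex <- rep(0:1, n / 2); vals$apoe4 <- rep(0:1, n / 2)
  vals$education <- rep(10:19, n / 10); vals$amyloid_stage <- rep(0:4, n / 5)
  vals$adni_mem <- pmin(pmax(x, -3), 3)
  vals$adni_ef <- pmin(pmax(y, -3), 3)
  co2 <- cohort_table(vals, rep("CN", n), dict)
  pm <- pearson_matrix(co2)
  expect_lt(abs(pm$correlation["adni_mem", "adni_ef"] - 0.6), 0.05)
  expect_gt(pm$report$frac_zero, 0.5)  # independent noise mostly zeroed
  expect_equal(diag(pm$correlation), rep(1, 19), ignore_attr = TRUE)
  # a constant column is reported as zero with a warning
  vals$education <- 16L
  co3 <- cohort_table(vals, rep("CN", n), dict)
  expect_warning(pm3 <- pearson_matrix(co3), "constant")
  expect_true(all(pm3$correlation["education", -3] == 0))
})

test_that("sparsity reports count unordered off-diagonal pairs", {
  expect_equal(sparsity_report(matrix(0, 4, 4)),
               list(avg_abs = 0, frac_zero = 1, frac_strong = 0,
                    strong_cut = 0.25))
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- 0.3
  M[1, 3] <- M[3, 1] <- -0.3
  # 2 of 3 pairs at |0.3| > 0.25, one at zero
  r <- sparsity_report(M)
  expect_equal(r$frac_zero, 1 / 3)
  expect_equal(r$frac_strong, 2 / 3)
  expect_equal(r$avg_abs, 0.2)
})
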