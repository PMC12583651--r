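## Synthetic cohort generator: a latent multivariate normal with a known
## sparse precision matrix, pushed through monotone margins that emulate the
## observed codings of a four-stage AD cohort (binary sex/APOE4, 5-level
## amyloid stage, integer education years, bounded cognitive composites,
## skewed positive imaging variables).

#' Ground-truth graphical model for simulation
#'
#' Builds a conditional-dependence graph and a matching symmetric
#' positive-definite precision matrix whose nonzero partial correlations have
#' absolute value within `[0.5, 1.5] * target_magnitude`. Off-diagonal
#' entries are assigned to the edges with random signs and magnitudes, the
#' diagonal is fixed at one, and the edge weights are shrunk (if necessary)
#' until the matrix passes a Cholesky check; with a unit diagonal the partial
#' correlation of an edge is simply minus its precision entry.
#'
#' `structure = "ad_motif"` is a fixed 19-node structure for demonstration
#' runs, wiring the memory—hippocampal-volume, executive-function—PCC-volume,
#' APOE4—amyloid and amyloid—memory dependencies together with age and sex
#' hubs and same-region volume—glucose couplings.
#'
#' @param p Number of nodes (>= 2); must be 19 for `"ad_motif"`.
#' @param structure `"random"` or `"ad_motif"`.
#' @param edge_density Expected fraction of present edges (`"random"` only).
#' @param target_magnitude Target absolute partial correlation in (0, 1).
#' @param seed Optional integer seed.
#' @return An object of class `"true_model"` with fields `adjacency` (p x p
#'   0/1), `precision`, `partial` (true partial correlations) and `edges`
#'   (data.frame `i`, `j`, `partial`).
#' @export
make_true_model <- function(p, structure = c("random", "ad_motif"),
                            edge_density = 0.2, target_magnitude = 0.2,
                            seed = NULL) {
  structure <- match.arg(structure)
  if (p < 2) stop("p must be at least 2")
  if (edge_density < 0 || edge_density > 1)
    stop("edge_density must lie in [0, 1]")
  if (target_magnitude <= 0 || target_magnitude >= 1)
    stop("target_magnitude must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (structure == "ad_motif") {
    if (p != 19) stop("ad_motif structure is defined for p = 19")
    nm <- dictionary_names(adni_dictionary("merged"))
    e <- function(a, b, s) data.frame(a = a, b = b, s = s)
    motif <- rbind(
      e("age", "amyloid_stage", +1), e("age", "vol_hippocampus", -1),
      e("age", "vol_PCC", -1), e("age", "vol_putamen", -1),
      e("age", "vol_thalamus", -1), e("age", "glu_caudate", -1),
      e("age", "adni_mem", +1), e("age", "adni_ef", -1),
      e("sex", "adni_mem", +1), e("sex", "education", -1),
      e("sex", "amyloid_stage", +1), e("sex", "vol_hippocampus", -1),
      e("sex", "vol_PCC", -1), e("sex", "vol_precuneus", -1),
      e("sex", "vol_putamen", +1),
      e("education", "adni_ef", +1),
      e("apoe4", "amyloid_stage", +1),
      e("amyloid_stage", "adni_mem", -1), e("amyloid_stage", "adni_ef", -1),
      e("vol_hippocampus", "adni_mem", +1), e("vol_PCC", "adni_ef", +1),
      e("vol_hippocampus", "glu_hippocampus", +1),
      e("vol_caudate", "glu_caudate", +1),
      e("vol_putamen", "glu_putamen", +1),
      e("vol_thalamus", "glu_thalamus", +1),
      e("vol_PCC", "glu_PCC", +1),
      e("vol_precuneus", "glu_precuneus", +1),
      e("vol_PCC", "glu_precuneus", +1),
      e("vol_precuneus", "glu_PCC", +1),
      e("vol_hippocampus", "glu_thalamus", +1))
    ii <- match(motif$a, nm); jj <- match(motif$b, nm)
    edges <- cbind(pmin(ii, jj), pmax(ii, jj))
    signs <- motif$s
    mags <- rep(target_magnitude, nrow(edges))
  } else {
    M <- p * (p - 1) / 2
    m <- round(edge_density * M)
    pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
    sel <- if (m > 0) sample(M, m) else integer(0)
    edges <- pairs[sel, , drop = FALSE]
    signs <- sample(c(-1, 1), m, replace = TRUE)
    mags <- target_magnitude * runif(m, 0.75, 1.25)
  }
  K <- diag(p)
  scale <- 1
  repeat {
    K[] <- 0; diag(K) <- 1
    for (r in seq_len(nrow(edges))) {
      v <- -signs[r] * mags[r] * scale
      K[edges[r, 1], edges[r, 2]] <- v
      K[edges[r, 2], edges[r, 1]] <- v
    }
    ok <- !inherits(try(chol(K), silent = TRUE), "try-error")
    if (ok) break
    scale <- scale * 0.9
    if (scale * max(c(mags, 0)) < 0.5 * target_magnitude)
      stop("could not build an SPD precision with partials in the target band")
  }
  partial <- partial_from_precision(K)
  adj <- matrix(0L, p, p)
  for (r in seq_len(nrow(edges))) {
    adj[edges[r, 1], edges[r, 2]] <- 1L
    adj[edges[r, 2], edges[r, 1]] <- 1L
  }
  if (nrow(edges) > 0) {
    band <- abs(partial[edges])
    if (any(band < 0.5 * target_magnitude | band > 1.5 * target_magnitude))
      stop("true partial correlations fell outside the target band")
  }
  structure(list(adjacency = adj, precision = K, partial = partial,
                 edges = data.frame(i = edges[, 1], j = edges[, 2],
                                    partial = partial[edges])),
            class = "true_model")
}

#' @export
print.true_model <- function(x, ...) {
  cat("True graphical model: p =", nrow(x$precision), ", edges =",
      nrow(x$edges), "\n")
  invisible(x)
}

.default_margins <- function() {
  list(
    sex = list(female_fraction = 0.47),
    apoe4 = list(carrier_fraction = 0.45),
    amyloid_stage = list(cut_probs = c(0.35, 0.55, 0.75, 0.90)),
    education = list(mean = 16.2, sd = 2.7, min = 0, max = 25),
    age = list(mean = 73.5, sd = 7.5),
    adni_mem = list(mean = 0.2, sd = 0.75, bound = 3),
    adni_ef = list(mean = 0.15, sd = 0.8, bound = 3),
    volume = list(base = c(hippocampus = 3.5, caudate = 3.4, putamen = 4.0,
                           thalamus = 6.3, PCC = 4.3, precuneus = 9.5),
                  skew = 0.35),
    glucose = list(base = c(hippocampus = 1.05, caudate = 1.25, putamen = 1.45,
                            thalamus = 1.3, PCC = 1.5, precuneus = 1.4),
                   skew = 0.25))
}

## Latent-scale group mean shifts that reproduce the qualitative baseline
## table of the study design (cognition CN > EMCI > LMCI > AD, amyloid and
## atrophy increasing with stage, female fraction 53/44/43/42%). Solved from
## the margin maps so the observed group means land near the published table.
.default_group_shifts <- function(dictionary, margins) {
  nm <- dictionary_names(dictionary)
  shifts <- matrix(0, 4, length(nm), dimnames = list(.diagnoses, nm))
  tab <- list(age = c(74.6, 71.6, 74.1, 75.1),
              education = c(16.5, 16.0, 16.2, 15.9),
              adni_mem = c(1.1, 0.58, 0.04, -0.91),
              adni_ef = c(0.83, 0.48, 0.14, -0.84),
              female = c(0.53, 0.44, 0.43, 0.42))
  tgt <- function(var) (tab[[var]] - margins[[var]]$mean) / margins[[var]]$sd
  for (v in c("age", "education", "adni_mem", "adni_ef"))
    if (v %in% nm) shifts[, v] <- tgt(v)
  if ("sex" %in% nm) {
    cut <- qnorm(1 - margins$sex$female_fraction)
    shifts[, "sex"] <- cut - qnorm(1 - tab$female)
  }
  if ("amyloid_stage" %in% nm)
    shifts[, "amyloid_stage"] <- c(-0.5, 0, 0.4, 0.9)
  if ("apoe4" %in% nm) shifts[, "apoe4"] <- c(-0.3, 0, 0.15, 0.5)
  vol_cols <- grep("^vol_", nm, value = TRUE)
  shifts[, vol_cols] <- rep(c(0.3, 0.1, -0.15, -0.6), length(vol_cols))
  glu_cols <- grep("^glu_", nm, value = TRUE)
  shifts[, glu_cols] <- rep(c(0.2, 0.05, -0.1, -0.45), length(glu_cols))
  shifts
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles everything the generator needs: the variable dictionary, the
#' ground-truth graphical model on the latent scale, per-group sample sizes
#' (defaults 345/297/205/175), per-group latent mean shifts and variance
#' scales (multipliers at most 1, emulating reduced within-group variance in
#' later disease stages), and the monotone margin maps that turn latent
#' Gaussians into observed codings.
#'
#' @param dictionary Variable dictionary; default [adni_dictionary()] merged.
#' @param true_model A [make_true_model()] result matching the dictionary
#'   size; default is the `ad_motif` structure.
#' @param group_sizes Named vector over CN/EMCI/LMCI/AD.
#' @param group_mean_shift 4 x p matrix of latent offsets (rows CN..AD);
#'   `NULL` for the cohort-emulating defaults, or `0` for none.
#' @param group_variance_scale Named per-group positive multipliers <= 1
#'   applied to latent standard deviations.
#' @param margins Margin parameter list; see `bgcgm:::.default_margins()`.
#' @param gaussian_margins If `TRUE`, the imaging margins become affine
#'   (instead of skewed exponential) so the semiparametric transform is the
#'   identity up to ranks — used for oracle tests.
#' @param seed Integer seed driving all generator randomness.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(dictionary = adni_dictionary("merged"),
                             true_model = NULL,
                             group_sizes = c(CN = 345, EMCI = 297,
                                             LMCI = 205, AD = 175),
                             group_mean_shift = NULL,
                             group_variance_scale = c(CN = 1, EMCI = 0.9,
                                                      LMCI = 0.85, AD = 0.8),
                             margins = .default_margins(),
                             gaussian_margins = FALSE,
                             seed = 1) {
  p <- length(dictionary$specs)
  if (is.null(true_model))
    true_model <- make_true_model(19, "ad_motif", seed = seed)
  if (nrow(true_model$precision) != p)
    stop("true_model size does not match the dictionary")
  if (!all(.diagnoses %in% names(group_sizes)))
    stop("group_sizes must name CN, EMCI, LMCI, AD")
  group_sizes <- group_sizes[.diagnoses]
  if (any(group_sizes < 0)) stop("group sizes must be non-negative")
  if (is.null(group_mean_shift)) {
    group_mean_shift <- .default_group_shifts(dictionary, margins)
  } else if (identical(group_mean_shift, 0)) {
    group_mean_shift <- matrix(0, 4, p, dimnames =
                                 list(.diagnoses, dictionary_names(dictionary)))
  }
  stopifnot(nrow(group_mean_shift) == 4, ncol(group_mean_shift) == p)
  group_variance_scale <- group_variance_scale[.diagnoses]
  if (any(group_variance_scale <= 0 | group_variance_scale > 1))
    stop("group_variance_scale must lie in (0, 1]")
  cp <- margins$amyloid_stage$cut_probs
  if (is.unsorted(cp, strictly = TRUE) || any(cp <= 0 | cp >= 1))
    stop("amyloid cut probabilities must be strictly increasing in (0, 1)")
  structure(list(dictionary = dictionary, true_model = true_model,
                 group_sizes = group_sizes,
                 group_mean_shift = group_mean_shift,
                 group_variance_scale = group_variance_scale,
                 margins = margins, gaussian_margins = gaussian_margins,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Draw the latent Gaussian matrix of a synthetic cohort
#'
#' Rows of diagnosis group g are drawn from N(mu_g, s_g^2 * K^-1) where K is
#' the true precision matrix, mu_g the group's latent mean shift and s_g its
#' variance scale. Deterministic given `config$seed`.
#'
#' @param model A [make_true_model()] result.
#' @param config A [generator_config()].
#' @return List with `Z` (n x p latent matrix) and `diagnosis` (labels).
#' @export
sample_latent <- function(model, config) {
  set.seed(config$seed)
  p <- nrow(model$precision)
  Sigma <- solve(model$precision)
  R <- chol(Sigma)
  Zs <- list(); dx <- character(0)
  for (g in .diagnoses) {
    ng <- config$group_sizes[[g]]
    if (ng == 0) next
    X <- matrix(rnorm(ng * p), ng, p) %*% R
    X <- X * config$group_variance_scale[[g]]
    X <- sweep(X, 2, config$group_mean_shift[g, ], `+`)
    Zs[[g]] <- X
    dx <- c(dx, rep(g, ng))
  }
  Z <- do.call(rbind, Zs)
  colnames(Z) <- dictionary_names(config$dictionary)
  list(Z = Z, diagnosis = dx)
}

#' Map latent Gaussians to observed codings
#'
#' Every observed column is a monotone nondecreasing function of its latent
#' column: thresholding for binary variables (the sex cut is placed so the
#' expected female fraction matches the configuration), quantile bins for the
#' five-level amyloid stage, rounding and clipping for education years, an
#' affine map for age, affine maps hard-clipped to \[-3, 3\] for the
#' cognitive composites, and strictly increasing exponential (skewed) maps
#' for volume and glucose — unless `gaussian_margins` makes those affine.
#' Deterministic (no randomness).
#'
#' @param latent Result of [sample_latent()] (list with `Z`, `diagnosis`).
#' @param config A [generator_config()].
#' @return A [cohort_table()].
#' @export
discretize_latent <- function(latent, config) {
  Z <- latent$Z
  dict <- config$dictionary
  if (ncol(Z) != length(dict$specs))
    stop("latent column count does not match the dictionary")
  mg <- config$margins
  out <- list()
  for (k in seq_along(dict$specs)) {
    s <- dict$specs[[k]]
    z <- Z[, k]
    out[[s$name]] <- switch(
      s$name,
      sex = as.integer(z > qnorm(1 - mg$sex$female_fraction)),
      apoe4 = as.integer(z > qnorm(1 - mg$apoe4$carrier_fraction)),
      amyloid_stage = {
        cuts <- qnorm(mg$amyloid_stage$cut_probs)
        as.integer(findInterval(z, cuts))
      },
      education = {
        e <- round(mg$education$mean + mg$education$sd * z)
        as.integer(pmin(pmax(e, mg$education$min), mg$education$max))
      },
      age = mg$age$mean + mg$age$sd * z,
      adni_mem = pmin(pmax(mg$adni_mem$mean + mg$adni_mem$sd * z,
                           -mg$adni_mem$bound), mg$adni_mem$bound),
      adni_ef = pmin(pmax(mg$adni_ef$mean + mg$adni_ef$sd * z,
                          -mg$adni_ef$bound), mg$adni_ef$bound),
      {
        par <- if (s$role == "volume") mg$volume else mg$glucose
        base <- par$base[[s$region]]
        if (config$gaussian_margins) base * (1 + 0.15 * z)
        else base * exp(par$skew * z)
      })
  }
  cohort_table(as.data.frame(out), latent$diagnosis, dict)
}

#' Generate a full synthetic cohort with known ground truth
#'
#' Composition of [sample_latent()] and [discretize_latent()]: draws the
#' latent matrix from the true model and pushes it through the monotone
#' margins. Byte-identical output for identical configurations and seeds.
#'
#' @param config A [generator_config()].
#' @return List with `cohort` (a [cohort_table()]), `model` (the ground
#'   truth) and `latent` (the latent matrix, for diagnostics).
#' @export
generate_cohort <- function(config) {
  lat <- sample_latent(config$true_model, config)
  cohort <- discretize_latent(lat, config)
  list(cohort = cohort, model = config$true_model, latent = lat$Z)
}
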