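#' @useDynLib bgcgm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats qnorm pnorm rnorm runif rgamma cor cor.test sd quantile
#'   density dnorm setNames complete.cases
#' @importFrom utils read.csv write.csv packageVersion head
NULL

## Controlled vocabularies for the cohort variable dictionary.
.regions <- c("hippocampus", "caudate", "putamen", "thalamus", "PCC", "precuneus")
.roles <- c("demographic", "cognitive", "genetic", "amyloid", "volume", "glucose")
.classes <- c("continuous", "discrete_count", "binary", "ordinal")
.diagnoses <- c("CN", "EMCI", "LMCI", "AD")

#' Describe one cohort variable
#'
#' A `variable_spec` records how a single column of a cohort table is coded:
#' its scientific role, its measurement class (which decides whether it is
#' transformed once before the chain or resampled inside it), and, for imaging
#' variables, the brain region and hemisphere it belongs to.
#'
#' @param name Short unique variable name (column header in cohort files).
#' @param role One of `"demographic"`, `"cognitive"`, `"genetic"`,
#'   `"amyloid"`, `"volume"`, `"glucose"`.
#' @param measurement_class One of `"continuous"`, `"discrete_count"`,
#'   `"binary"`, `"ordinal"`.
#' @param levels Ordered integer codes; required for binary (exactly `0:1`)
#'   and ordinal (the amyloid stage uses `0:4`) variables.
#' @param region Brain region for volume/glucose variables, one of
#'   `r paste(.regions, collapse = ", ")`; must be absent otherwise.
#' @param hemisphere `"left"`, `"right"` or `"merged"` for region variables.
#' @return An object of class `"variable_spec"`.
#' @export
variable_spec <- function(name, role, measurement_class, levels = NULL,
                          region = NULL, hemisphere = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, .roles)
  measurement_class <- match.arg(measurement_class, .classes)
  if (measurement_class == "binary") {
    if (is.null(levels)) levels <- 0:1
    if (!identical(as.integer(levels), 0:1))
      stop("binary variable '", name, "' must have levels {0, 1}")
  }
  if (measurement_class == "ordinal") {
    if (is.null(levels) || length(levels) < 2L)
      stop("ordinal variable '", name, "' needs ordered integer levels")
    levels <- as.integer(levels)
    if (is.unsorted(levels, strictly = TRUE))
      stop("levels of '", name, "' must be strictly increasing")
  }
  if (role %in% c("volume", "glucose")) {
    if (is.null(region)) stop("'", name, "' (", role, ") must carry a region")
    region <- match.arg(region, .regions)
    if (is.null(hemisphere)) hemisphere <- "merged"
    hemisphere <- match.arg(hemisphere, c("left", "right", "merged"))
  } else {
    if (!is.null(region))
      stop("'", name, "' (", role, ") must not carry a region")
    hemisphere <- NULL
  }
  structure(list(name = name, role = role,
                 measurement_class = measurement_class,
                 levels = if (!is.null(levels)) as.integer(levels),
                 region = region, hemisphere = hemisphere),
            class = "variable_spec")
}

new_variable_dictionary <- function(specs, mode) {
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate variable names in dictionary")
  roles <- vapply(specs, `[[`, "", "role")
  counts <- table(factor(roles, levels = .roles))
  expected <- c(demographic = 3L, cognitive = 2L, genetic = 1L, amyloid = 1L,
                volume = if (mode == "merged") 6L else 12L,
                glucose = if (mode == "merged") 6L else 12L)
  if (!all(counts[names(expected)] == expected))
    stop("dictionary role counts do not match ", mode, " mode")
  ptot <- if (mode == "merged") 19L else 31L
  if (length(specs) != ptot)
    stop(mode, " dictionary must contain exactly ", ptot, " variables")
  structure(list(specs = specs, mode = mode),
            class = "variable_dictionary")
}

#' Study variable dictionary (19 merged or 31 split variables)
#'
#' Builds the full variable dictionary of the cohort design: three
#' demographics (age, sex, education), two cognitive composites (memory and
#' executive function, each bounded in \[-3, 3\]), APOE4 carrier status, a
#' five-level ordinal amyloid stage, and gray-matter volume plus glucose
#' uptake for six brain regions. In `"merged"` mode left/right hemispheres
#' are averaged (19 variables); in `"split"` mode each region contributes a
#' left and a right variable (31 variables).
#'
#' @param mode `"merged"` (default) or `"split"`.
#' @return A `variable_dictionary` with fields `specs` (ordered list of
#'   [variable_spec()]) and `mode`.
#' @export
adni_dictionary <- function(mode = c("merged", "split")) {
  mode <- match.arg(mode)
  specs <- list(
    variable_spec("age", "demographic", "continuous"),
    variable_spec("sex", "demographic", "binary"),
    variable_spec("education", "demographic", "discrete_count"),
    variable_spec("adni_mem", "cognitive", "continuous"),
    variable_spec("adni_ef", "cognitive", "continuous"),
    variable_spec("apoe4", "genetic", "binary"),
    variable_spec("amyloid_stage", "amyloid", "ordinal", levels = 0:4))
  region_specs <- function(role, prefix) {
    if (mode == "merged") {
      lapply(.regions, function(r)
        variable_spec(paste0(prefix, "_", r), role, "continuous",
                      region = r, hemisphere = "merged"))
    } else {
      unlist(lapply(.regions, function(r)
        lapply(c("left", "right"), function(h)
          variable_spec(paste0(prefix, "_", r, "_", h), role, "continuous",
                        region = r, hemisphere = h))), recursive = FALSE)
    }
  }
  specs <- c(specs, region_specs("volume", "vol"), region_specs("glucose", "glu"))
  new_variable_dictionary(specs, mode)
}

#' @export
print.variable_dictionary <- function(x, ...) {
  cat("Variable dictionary (", x$mode, " mode): ",
      length(x$specs), " variables\n", sep = "")
  df <- data.frame(name = dictionary_names(x),
                   role = vapply(x$specs, `[[`, "", "role"),
                   class = vapply(x$specs, `[[`, "", "measurement_class"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Variable names of a dictionary, in dictionary order
#' @param dictionary A `variable_dictionary`.
#' @return Character vector of variable names.
#' @export
dictionary_names <- function(dictionary) {
  vapply(dictionary$specs, `[[`, "", "name")
}

#' Which dictionary columns are treated as discrete in the copula layer
#'
#' Binary, ordinal and count variables are resampled inside the MCMC chain
#' (extended rank likelihood); continuous variables — including age, which is
#' recorded in whole years but treated as continuous — are transformed once.
#'
#' @param dictionary A `variable_dictionary`.
#' @return Logical vector over dictionary positions.
#' @export
discrete_mask <- function(dictionary) {
  vapply(dictionary$specs, function(s)
    s$measurement_class %in% c("binary", "ordinal", "discrete_count"), NA)
}

#' Serialize / read a dictionary as YAML
#' @param dictionary A `variable_dictionary`.
#' @param path File path.
#' @return `read_dictionary` returns a `variable_dictionary`;
#'   `write_dictionary` returns `path` invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  specs <- lapply(dictionary$specs, function(s) s[!vapply(s, is.null, NA)])
  yaml::write_yaml(list(mode = dictionary$mode, variables = specs), path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw$variables, function(s)
    variable_spec(s$name, s$role, s$measurement_class, levels = s$levels,
                  region = s$region, hemisphere = s$hemisphere))
  new_variable_dictionary(specs, raw$mode)
}
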