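#' Construct and validate a cohort table
#'
#' A cohort table holds the observed mixed-type data: one row per participant,
#' one column per dictionary variable, plus a diagnosis label (CN, EMCI, LMCI
#' or AD) that is metadata only and never enters the model as a node. The
#' constructor enforces the coding contract: binary variables in \{0, 1\},
#' ordinal variables in their level set, count variables as non-negative
#' integers, cognitive composites in \[-3, 3\], and no missing values
#' (complete cases only — missingness is a hard error, not imputed).
#'
#' @param values Data frame of observed variables (any column order; columns
#'   are reordered to dictionary order).
#' @param diagnosis Vector of diagnosis labels, one per row.
#' @param dictionary A [variable_dictionary][adni_dictionary].
#' @return An object of class `"cohort_table"` with fields `values`
#'   (data.frame in dictionary order), `diagnosis` (factor) and `dictionary`.
#' @export
cohort_table <- function(values, diagnosis, dictionary) {
  nm <- dictionary_names(dictionary)
  missing_cols <- setdiff(nm, names(values))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  values <- as.data.frame(values)[nm]
  n <- nrow(values)
  if (length(diagnosis) != n)
    stop("diagnosis must have one label per row")
  diagnosis <- as.character(diagnosis)
  bad_dx <- which(!diagnosis %in% .diagnoses)
  if (length(bad_dx) > 0)
    stop("unknown diagnosis label in row ", bad_dx[1], ": ", diagnosis[bad_dx[1]])
  for (s in dictionary$specs) {
    x <- values[[s$name]]
    if (!is.numeric(x)) stop("column '", s$name, "' must be numeric")
    if (anyNA(x))
      stop("missing value in column '", s$name, "' at row ", which(is.na(x))[1],
           " (complete cases required; no imputation is performed)")
    if (s$measurement_class %in% c("binary", "ordinal")) {
      bad <- which(!x %in% s$levels)
      if (length(bad) > 0)
        stop("column '", s$name, "' has out-of-range code ", x[bad[1]],
             " at row ", bad[1])
      values[[s$name]] <- as.integer(x)
    } else if (s$measurement_class == "discrete_count") {
      bad <- which(x < 0 | x != round(x))
      if (length(bad) > 0)
        stop("column '", s$name, "' must be a non-negative integer; row ",
             bad[1], " has ", x[bad[1]])
      values[[s$name]] <- as.integer(x)
    } else if (s$role == "cognitive") {
      bad <- which(x < -3 | x > 3)
      if (length(bad) > 0)
        stop("column '", s$name, "' must lie in [-3, 3]; row ", bad[1],
             " has ", x[bad[1]])
    }
    if (any(!is.finite(values[[s$name]])))
      stop("non-finite value in column '", s$name, "'")
  }
  structure(list(values = values,
                 diagnosis = factor(diagnosis, levels = .diagnoses),
                 dictionary = dictionary),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table: ", nrow(x$values), " participants x ",
      ncol(x$values), " variables (", x$dictionary$mode, " dictionary)\n",
      sep = "")
  print(table(x$diagnosis))
  invisible(x)
}

#' Number of participants / variables in a cohort
#' @param cohort A `cohort_table`.
#' @return Integer.
#' @export
cohort_n <- function(cohort) nrow(cohort$values)

#' @rdname cohort_n
#' @export
cohort_p <- function(cohort) ncol(cohort$values)

#' Read a cohort CSV against a dictionary
#'
#' The file must have a header row naming every dictionary variable plus a
#' `diagnosis` column (UTF-8, period decimal separator). Column order in the
#' file is irrelevant; the returned table follows dictionary order. Any
#' missing column, out-of-range code or missing cell is an error naming the
#' offending column/row.
#'
#' @param path CSV file path.
#' @param dictionary A [variable_dictionary][adni_dictionary].
#' @return A validated [cohort_table()].
#' @export
load_cohort <- function(path, dictionary) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (!"diagnosis" %in% names(df))
    stop("missing column(s): diagnosis")
  cohort_table(df[setdiff(names(df), "diagnosis")], df$diagnosis, dictionary)
}

#' Write a cohort table to CSV
#' @param cohort A `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cbind(cohort$values, diagnosis = as.character(cohort$diagnosis))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset cohort rows
#' @param cohort A `cohort_table`.
#' @param rows Integer or logical row index.
#' @return A `cohort_table` with the selected rows.
#' @export
cohort_subset <- function(cohort, rows) {
  cohort_table(cohort$values[rows, , drop = FALSE],
               as.character(cohort$diagnosis)[rows], cohort$dictionary)
}

#' Average left and right hemispheres
#'
#' Collapses a 31-variable (split) cohort to the 19-variable (merged) design:
#' each region/modality pair becomes the unweighted arithmetic mean of its
#' left and right values; non-region variables pass through unchanged.
#'
#' @param cohort A `cohort_table` over the split dictionary.
#' @return A `cohort_table` over the merged dictionary.
#' @export
merge_hemispheres <- function(cohort) {
  if (cohort$dictionary$mode != "split")
    stop("cohort is already in merged mode")
  merged_dict <- adni_dictionary("merged")
  vals <- cohort$values
  out <- list()
  for (s in merged_dict$specs) {
    if (s$role %in% c("volume", "glucose")) {
      left <- vals[[paste0(s$name, "_left")]]
      right <- vals[[paste0(s$name, "_right")]]
      out[[s$name]] <- (left + right) / 2
    } else {
      out[[s$name]] <- vals[[s$name]]
    }
  }
  cohort_table(as.data.frame(out), as.character(cohort$diagnosis), merged_dict)
}

#' Per-diagnosis cohort summary
#'
#' Reproduces the usual baseline characteristics table: per diagnosis group
#' (and a pooled Total row) the sample size, percent female, and mean (SD) of
#' age, education and the two cognitive composites. Empty groups report size
#' 0 and `NA` statistics.
#'
#' @param cohort A `cohort_table`.
#' @return A data.frame with one row per group plus `"Total"`.
#' @export
summarize_cohort <- function(cohort) {
  groups <- c(levels(cohort$diagnosis), "Total")
  one <- function(g) {
    rows <- if (g == "Total") rep(TRUE, cohort_n(cohort))
            else cohort$diagnosis == g
    v <- cohort$values[rows, , drop = FALSE]
    n <- nrow(v)
    stat <- function(x, f) if (n == 0) NA_real_ else f(x)
    data.frame(group = g, n = n,
               pct_female = stat(v$sex, function(x) 100 * mean(x)),
               age_mean = stat(v$age, mean), age_sd = stat(v$age, sd),
               education_mean = stat(v$education, mean),
               education_sd = stat(v$education, sd),
               adni_mem_mean = stat(v$adni_mem, mean),
               adni_mem_sd = stat(v$adni_mem, sd),
               adni_ef_mean = stat(v$adni_ef, mean),
               adni_ef_sd = stat(v$adni_ef, sd))
  }
  out <- do.call(rbind, lapply(groups, one))
  rownames(out) <- NULL
  out
}
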