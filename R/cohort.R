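#' Cohort table container
#'
#' A `cohort_table` bundles everything one prospective-cohort analysis needs:
#' a samples x metabolites feature matrix (missing values as `NA`), per-feature
#' metadata (panel of origin, identification status), a clinical covariate
#' table and the binary progression outcome (1 = progressor, 0 =
#' non-progressor).
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param features numeric matrix, samples x features, with column names;
#'   missing measurements are `NA`.
#' @param feature_meta data.frame with columns `name`, `panel`
#'   (`"targeted"`/`"untargeted"`) and `identified` (`"yes"`/`"no"`), one row
#'   per feature column.
#' @param covariates data.frame of per-sample clinical variables (may contain
#'   `NA`).
#' @param outcome integer/logical vector, 1 for progressors.
#'
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(sample_ids, features, feature_meta, covariates, outcome) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  outcome <- as_01(outcome)
  x <- structure(
    list(
      sample_ids = as.character(sample_ids),
      features = features,
      feature_meta = feature_meta,
      covariates = covariates,
      outcome = outcome
    ),
    class = "cohort_table"
  )
  validate_cohort_table(x)
  x
}

validate_cohort_table <- function(x) {
  n <- length(x$sample_ids)
  if (nrow(x$features) != n) stopf("feature matrix has %d rows for %d samples", nrow(x$features), n)
  if (length(x$outcome) != n) stopf("outcome length %d does not match %d samples", length(x$outcome), n)
  if (!is.null(x$covariates) && nrow(x$covariates) != n) {
    stopf("covariate table has %d rows for %d samples", nrow(x$covariates), n)
  }
  if (anyDuplicated(x$sample_ids)) {
    stopf("duplicated sample id: %s", x$sample_ids[duplicated(x$sample_ids)][1])
  }
  fn <- colnames(x$features)
  if (is.null(fn) || anyDuplicated(fn)) stopf("feature names must be present and unique")
  if (!is.null(x$feature_meta)) {
    if (!identical(x$feature_meta$name, fn)) stopf("feature_meta rows must align with feature columns")
  }
  if (length(unique(x$outcome)) < 2L) stopf("outcome must contain both classes")
  invisible(x)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "cohort_table: %d samples x %d features (%d progressors, %d non-progressors)\n",
    length(x$sample_ids), ncol(x$features), sum(x$outcome == 1), sum(x$outcome == 0)
  ))
  if (!is.null(x$feature_meta)) {
    cat(sprintf(
      "  panels: %d targeted, %d untargeted; missing cells: %d\n",
      sum(x$feature_meta$panel == "targeted"),
      sum(x$feature_meta$panel == "untargeted"),
      sum(is.na(x$features))
    ))
  }
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples / features of a cohort
#' @param x a `cohort_table`.
#' @return integer count.
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname n_samples
#' @export
n_features <- function(x) ncol(x$features)

# Subset a cohort by sample index and/or feature names, keeping all components
# aligned. Internal: user-facing subsetting goes through the preprocessing ops.
subset_cohort <- function(x, samples = NULL, feature_names = NULL) {
  if (!is.null(samples)) {
    x$sample_ids <- x$sample_ids[samples]
    x$features <- x$features[samples, , drop = FALSE]
    x$covariates <- x$covariates[samples, , drop = FALSE]
    x$outcome <- x$outcome[samples]
  }
  if (!is.null(feature_names)) {
    missing <- setdiff(feature_names, colnames(x$features))
    if (length(missing)) stopf("unknown feature name(s): %s", paste(missing, collapse = ", "))
    x$features <- x$features[, feature_names, drop = FALSE]
    x$feature_meta <- x$feature_meta[match(feature_names, x$feature_meta$name), , drop = FALSE]
    rownames(x$feature_meta) <- NULL
  }
  x
}
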