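#' Minimum imputation of missing metabolite measurements
#'
#' Replaces every missing cell of a feature by that feature's minimum observed
#' value, the standard convention for intensities below the detection limit.
#' Observed cells are untouched.
#'
#' @param table a [cohort_table()]; every feature must have at least one
#'   observed value.
#' @return The cohort with a complete feature matrix.
#' @export
impute_minimum <- function(table) {
  X <- table$features
  nmiss <- colSums(is.na(X))
  if (any(nmiss == nrow(X))) {
    stopf("feature(s) with no observed values: %s",
          paste(colnames(X)[nmiss == nrow(X)], collapse = ", "))
  }
  for (j in which(nmiss > 0)) {
    X[is.na(X[, j]), j] <- min(X[, j], na.rm = TRUE)
  }
  table$features <- X
  table
}

#' Per-feature standardisation to zero mean and unit variance
#'
#' Centres and scales every feature column (sample SD, n-1 denominator) and
#' returns the parameters so the identical affine map can be applied to
#' external data via [standardise_apply()] without re-centring leakage.
#'
#' @param table a [cohort_table()] with a complete feature matrix (impute
#'   first).
#' @return list with elements `table` (standardised cohort) and `params`
#'   (object of class `standardisation_params`: per-feature `mean` and `sd`).
#' @export
standardise <- function(table) {
  X <- table$features
  if (anyNA(X)) stopf("feature matrix contains missing values; impute first")
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd1)
  bad <- !is.finite(sigma) | sigma <= 0
  if (any(bad)) {
    stopf("constant feature(s), SD undefined: %s", paste(colnames(X)[bad], collapse = ", "))
  }
  params <- structure(
    list(feature = colnames(X), mean = mu, sd = sigma),
    class = "standardisation_params"
  )
  table$features <- sweep(sweep(X, 2, mu, "-"), 2, sigma, "/")
  list(table = table, params = params)
}

#' Apply previously computed standardisation parameters
#'
#' @param table a [cohort_table()] whose features are a subset of
#'   `params$feature`.
#' @param params a `standardisation_params` object from [standardise()].
#' @return The cohort transformed with the stored means/SDs.
#' @export
standardise_apply <- function(table, params) {
  X <- table$features
  idx <- match(colnames(X), params$feature)
  if (anyNA(idx)) {
    stopf("no standardisation parameters for feature(s): %s",
          paste(colnames(X)[is.na(idx)], collapse = ", "))
  }
  table$features <- sweep(sweep(X, 2, params$mean[idx], "-"), 2, params$sd[idx], "/")
  table
}

#' Merge targeted and untargeted panels into one feature matrix
#'
#' Column-concatenates two cohorts measured on the same samples; feature
#' metadata keeps each feature's panel of origin.
#'
#' @param targeted,untargeted [cohort_table()]s with identical `sample_ids` in
#'   identical order and disjoint feature names. Covariates and outcome are
#'   taken from `targeted` (they must agree on the outcome).
#' @return The merged [cohort_table()].
#' @export
merge_panels <- function(targeted, untargeted) {
  if (!identical(targeted$sample_ids, untargeted$sample_ids)) {
    diff <- which(targeted$sample_ids != untargeted$sample_ids)[1]
    if (is.na(diff)) diff <- min(length(targeted$sample_ids), length(untargeted$sample_ids)) + 1L
    stopf("sample ids differ between panels (first difference at position %d)", diff)
  }
  if (!identical(targeted$outcome, untargeted$outcome)) stopf("outcomes differ between panels")
  dup <- intersect(colnames(targeted$features), colnames(untargeted$features))
  if (length(dup)) stopf("duplicate feature name(s): %s", paste(dup, collapse = ", "))
  if (ncol(untargeted$features) == 0L) return(targeted)
  targeted$features <- cbind(targeted$features, untargeted$features)
  targeted$feature_meta <- rbind(targeted$feature_meta, untargeted$feature_meta)
  rownames(targeted$feature_meta) <- NULL
  validate_cohort_table(targeted)
  targeted
}

#' Exclude samples with missing values in required covariates
#'
#' Implements the per-analysis exclusion rule: only analyses involving a
#' clinical factor drop the samples missing it, so the returned cohort is
#' specific to one adjustment set.
#'
#' @param table a [cohort_table()].
#' @param covariates character vector of required covariate names (empty
#'   vector returns the table unchanged).
#' @return The complete-case sub-cohort for those covariates.
#' @export
exclude_missing_covariates <- function(table, covariates) {
  if (length(covariates) == 0L) return(table)
  absent <- setdiff(covariates, names(table$covariates))
  if (length(absent)) stopf("unknown covariate(s): %s", paste(absent, collapse = ", "))
  keep <- !Reduce(`|`, lapply(covariates, function(v) is.na(table$covariates[[v]])))
  if (!any(keep)) stopf("no samples with complete %s", paste(covariates, collapse = ", "))
  out <- subset_cohort(table, samples = which(keep))
  if (length(unique(out$outcome)) < 2L) {
    stopf("complete-case cohort for %s has a single outcome class", paste(covariates, collapse = ", "))
  }
  out
}
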