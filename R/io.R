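# Reading and writing the plain-text cohort interchange format: a features
# table and a covariates+outcome table (TSV or CSV by extension), missing
# values as empty fields, plus JSON sidecars for configs and models.

delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Write a cohort as two delimited text files
#'
#' @param table a [cohort_table()].
#' @param features_path,covariates_path output paths (`.tsv` or `.csv`); the
#'   first column is the sample id, missing values are written as empty
#'   fields. The covariates file carries the covariates plus an `outcome`
#'   column.
#' @param config optional [synthetic_config()] written as a JSON sidecar next
#'   to the features file.
#' @return invisibly, the feature path.
#' @export
write_cohort <- function(table, features_path, covariates_path, config = NULL) {
  fdf <- data.frame(sample_id = table$sample_ids, table$features,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(fdf, features_path, sep = delim_for(features_path),
                     quote = FALSE, row.names = FALSE, na = "")
  cdf <- data.frame(sample_id = table$sample_ids, table$covariates,
                    outcome = table$outcome, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cdf, covariates_path, sep = delim_for(covariates_path),
                     quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(config)) {
    side <- sub("\\.[^.]+$", ".config.json", features_path)
    cfg <- unclass(config)
    cfg$covariate_model <- lapply(cfg$covariate_model, function(m) {
      if (m$type == "categorical") m$prob <- as.data.frame(m$prob)
      m
    })
    jsonlite::write_json(cfg, side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(features_path)
}

read_delim_checked <- function(path) {
  df <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), quote = "")
  if (!"sample_id" %in% names(df)[1]) stopf("%s: first column must be sample_id", path)
  if (anyDuplicated(df$sample_id)) {
    stopf("%s: duplicated sample id %s", path, df$sample_id[duplicated(df$sample_id)][1])
  }
  df
}

#' Read a cohort from delimited text files
#'
#' Inverse of [write_cohort()]: expects a features table and a covariates
#' table sharing the same sample ids, comma- or tab-delimited by extension.
#' Missing values are empty fields or `NA`.
#'
#' @param features_path,covariates_path input paths.
#' @param feature_meta optional feature metadata data.frame (columns `name`,
#'   `panel`, `identified`); defaults to all-untargeted.
#' @return a [cohort_table()].
#' @export
read_cohort <- function(features_path, covariates_path, feature_meta = NULL) {
  fdf <- read_delim_checked(features_path)
  cdf <- read_delim_checked(covariates_path)
  if (!identical(fdf$sample_id, cdf$sample_id)) {
    stopf("sample ids differ between %s and %s", features_path, covariates_path)
  }
  X <- as.matrix(fdf[-1])
  if (!is.numeric(X)) {
    bad <- which(!vapply(fdf[-1], is.numeric, logical(1)))[1]
    stopf("non-numeric feature column: %s", names(fdf[-1])[bad])
  }
  if (!"outcome" %in% names(cdf)) stopf("%s: missing outcome column", covariates_path)
  covs <- cdf[setdiff(names(cdf), c("sample_id", "outcome"))]
  if (is.null(feature_meta)) {
    feature_meta <- data.frame(name = colnames(X), panel = "untargeted",
                               identified = "yes", stringsAsFactors = FALSE)
  }
  cohort_table(fdf$sample_id, X, feature_meta, covs, cdf$outcome)
}

#' Serialise an RLS model to JSON
#'
#' @param model an `rls_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rls_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an RLS model from JSON
#' @param path path written by [write_rls_model()].
#' @return an `rls_model`.
#' @export
read_rls_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$weights <- stats::setNames(as.numeric(m$weights), m$feature_names)
  structure(m, class = "rls_model")
}

#' Serialise standardisation parameters to JSON
#' @param params from [standardise()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_standardisation <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read standardisation parameters from JSON
#' @param path path written by [write_standardisation()].
#' @return a `standardisation_params` object.
#' @export
read_standardisation <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(feature = p$feature, mean = as.numeric(p$mean), sd = as.numeric(p$sd)),
            class = "standardisation_params")
}

#' Write per-repetition out-of-fold scores as TSV
#'
#' Long format: sample_id, repetition, fold, score.
#'
#' @param result a [nested_cv()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_scores <- function(result, path) {
  R <- ncol(result$scores)
  n <- nrow(result$scores)
  df <- data.frame(
    sample_id = rep(rownames(result$scores), R),
    repetition = rep(seq_len(R), each = n),
    fold = as.vector(result$folds),
    score = as.vector(result$scores),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
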