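# Repeated nested stratified cross-validation: performance estimation, inner
# selection of the regularisation parameter, per-repetition marker selection,
# panel union and external-cohort transfer.

#' Cross-validation plan
#'
#' @param outer_folds,inner_folds fold counts (>= 2); defaults 10 and 10.
#' @param repetitions number of repeated runs (default 100). Repetition r uses
#'   seed `seed + r`, so any repetition is reproducible in isolation.
#' @param seed base seed.
#' @return object of class `cv_plan`.
#' @export
cv_plan <- function(outer_folds = 10L, inner_folds = 10L, repetitions = 100L, seed = 1L) {
  if (outer_folds < 2L || inner_folds < 2L) stopf("fold counts must be >= 2")
  if (repetitions < 1L) stopf("repetitions must be >= 1")
  structure(
    list(outer_folds = as.integer(outer_folds), inner_folds = as.integer(inner_folds),
         repetitions = as.integer(repetitions), seed = as.integer(seed)),
    class = "cv_plan"
  )
}

#' Stratified fold assignment
#'
#' Partitions samples into folds so that, within each outcome class, fold
#' counts differ by at most one. Pure function of the seed.
#'
#' @param outcome binary vector.
#' @param n_folds number of folds (at most the minority-class count).
#' @param seed integer.
#' @return integer vector of fold labels in 1..n_folds.
#' @export
stratified_folds <- function(outcome, n_folds, seed = 1L) {
  y <- as_01(outcome)
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  minority <- min(table(y))
  if (n_folds > minority) {
    stopf("n_folds (%d) exceeds the minority class count (%d)", n_folds, minority)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

# Most frequent value; ties broken by the smallest.
modal_value <- function(x) {
  tab <- table(x)
  min(as.numeric(names(tab)[tab == max(tab)]))
}

# Numeric model matrix for a feature set plus clinical covariates. Covariate
# dummies/columns are standardised on the analysis cohort so the ridge penalty
# treats all columns comparably (features are assumed standardised upstream).
build_model_matrix <- function(table, feature_set = character(), covariate_set = character()) {
  parts <- list()
  if (length(feature_set)) {
    missing <- setdiff(feature_set, colnames(table$features))
    if (length(missing)) stopf("unknown feature(s): %s", paste(missing, collapse = ", "))
    parts$features <- table$features[, feature_set, drop = FALSE]
  }
  if (length(covariate_set)) {
    D <- covariate_design(table, covariate_set)
    sds <- apply(D, 2, sd1)
    if (any(sds == 0)) stopf("constant covariate column(s): %s", paste(colnames(D)[sds == 0], collapse = ", "))
    parts$covariates <- sweep(sweep(D, 2, colMeans(D), "-"), 2, sds, "/")
  }
  if (!length(parts)) stopf("empty model: no features and no covariates")
  do.call(cbind, parts)
}

# Inner-CV lambda choice for one outer-training set: pooled inner out-of-fold
# AUC per grid value, ties -> smallest lambda.
choose_lambda <- function(D, K, y01, tr, inner_folds, lambdas, intercept, seed,
                          criterion = "auc") {
  inner <- stratified_folds(y01[tr], inner_folds, seed)
  oof <- matrix(NA_real_, length(tr), length(lambdas))
  for (g in seq_len(inner_folds)) {
    tr2 <- tr[inner != g]
    te2 <- tr[inner == g]
    oof[inner == g, ] <- if (is.null(K)) {
      lambda_scores_primal(D, y01 * 2 - 1, tr2, te2, lambdas, intercept)
    } else {
      lambda_scores_kernel(K, y01 * 2 - 1, tr2, te2, lambdas, intercept)
    }
  }
  crit <- if (criterion == "auc") {
    apply(oof, 2, auc, labels = y01[tr])
  } else {
    -colMeans((oof - (y01[tr] * 2 - 1))^2)
  }
  lambdas[which.max(crit)] # first max = smallest lambda on the sorted grid
}

#' Repeated nested stratified cross-validation for an RLS model
#'
#' Per repetition: a fresh stratified outer split (repetition r seeded with
#' `plan$seed + r`); per outer fold, inner stratified cross-validation on the
#' outer-training samples picks the grid lambda maximising pooled inner
#' out-of-fold AUC; when `select_k` is given, GreedyRLS restricted to
#' `select_k` features runs on the outer-training data at that lambda before
#' the refit; the refit model scores the outer-test samples. The
#' per-repetition ROC/AUC is built from the pooled out-of-fold scores. When
#' selection is enabled, the reported per-repetition feature list is GreedyRLS
#' run on the entire cohort with the modal lambda across that repetition's
#' outer folds (`selection_scope = "full-cohort"`, the default) or the union
#' of the per-fold selections (`"fold-union"`).
#'
#' @param table a preprocessed [cohort_table()].
#' @param feature_set metabolite feature names entering the model (may be
#'   empty when `covariate_set` is not).
#' @param config an [rls_config()]; its `lambda_grid` is searched.
#' @param plan a [cv_plan()].
#' @param select_k optional panel size for in-fold GreedyRLS (metabolite
#'   features only; incompatible with `covariate_set`).
#' @param covariate_set clinical covariate names included as (standardised)
#'   model columns.
#' @param selection_scope how the reported per-repetition feature list is
#'   derived, see above.
#' @param standardise_foldwise re-standardise the design within each outer
#'   training fold (leakage-free variant; default FALSE matches the global
#'   preprocessing convention).
#' @param inner_criterion "auc" (default) or "mse" for inner lambda choice.
#' @param model_spec label carried into reports.
#' @return object of class `nested_cv_result`; see Details.
#' @details The result stores per-repetition out-of-fold `scores` (samples x
#'   repetitions), fold assignments, per-fold chosen `lambdas`, per-repetition
#'   `auc`, the modal lambda per repetition, and (with selection) the
#'   per-repetition reported feature lists plus `auc_full`/`full_scores` for
#'   the same-lambda model on all features.
#' @export
nested_cv <- function(table, feature_set, config = rls_config(), plan = cv_plan(),
                      select_k = NULL, covariate_set = character(),
                      selection_scope = c("full-cohort", "fold-union"),
                      standardise_foldwise = FALSE,
                      inner_criterion = c("auc", "mse"),
                      model_spec = "custom") {
  selection_scope <- match.arg(selection_scope)
  inner_criterion <- match.arg(inner_criterion)
  if (!is.null(select_k) && length(covariate_set)) {
    stopf("select_k applies to metabolite-only models; drop covariate_set")
  }
  D <- build_model_matrix(table, feature_set, covariate_set)
  y01 <- table$outcome
  ypm <- y01 * 2 - 1
  n <- length(y01)
  R <- plan$repetitions
  use_kernel <- ncol(D) > n && !standardise_foldwise
  K <- if (use_kernel) tcrossprod(D) else NULL
  scores <- matrix(NA_real_, n, R, dimnames = list(table$sample_ids, NULL))
  full_scores <- if (!is.null(select_k)) scores else NULL
  folds_mat <- matrix(NA_integer_, n, R)
  lambdas_mat <- matrix(NA_real_, plan$outer_folds, R)
  selections <- if (!is.null(select_k)) vector("list", R) else NULL
  fold_selections <- if (!is.null(select_k)) vector("list", R) else NULL
  for (r in seq_len(R)) {
    seed_r <- plan$seed + r
    outer <- stratified_folds(y01, plan$outer_folds, seed_r)
    folds_mat[, r] <- outer
    fold_sel_r <- vector("list", plan$outer_folds)
    for (f in seq_len(plan$outer_folds)) {
      tr <- which(outer != f)
      te <- which(outer == f)
      Df <- D
      if (standardise_foldwise) {
        mu <- colMeans(D[tr, , drop = FALSE])
        sg <- apply(D[tr, , drop = FALSE], 2, sd1)
        sg[sg == 0] <- 1
        Df <- sweep(sweep(D, 2, mu, "-"), 2, sg, "/")
      }
      lam <- choose_lambda(Df, K, y01, tr, plan$inner_folds, config$lambda_grid,
                           config$intercept, mix_seed(seed_r, f), inner_criterion)
      lambdas_mat[f, r] <- lam
      cfg_f <- rls_config(lambda = lam, lambda_grid = config$lambda_grid,
                          intercept = config$intercept)
      if (!is.null(select_k)) {
        sel <- greedy_rls_select(Df[tr, , drop = FALSE], ypm[tr], cfg_f, select_k)
        fold_sel_r[[f]] <- sel$ordered_features
        m <- fit_rls(Df[tr, sel$ordered_features, drop = FALSE], ypm[tr], cfg_f)
        scores[te, r] <- predict(m, Df[te, sel$ordered_features, drop = FALSE])
        full_scores[te, r] <- if (is.null(K)) {
          lambda_scores_primal(Df, ypm, tr, te, lam, config$intercept)
        } else {
          lambda_scores_kernel(K, ypm, tr, te, lam, config$intercept)
        }
      } else {
        scores[te, r] <- if (is.null(K)) {
          lambda_scores_primal(Df, ypm, tr, te, lam, config$intercept)
        } else {
          lambda_scores_kernel(K, ypm, tr, te, lam, config$intercept)
        }
      }
    }
    if (!is.null(select_k)) {
      fold_selections[[r]] <- fold_sel_r
      lam_r <- modal_value(lambdas_mat[, r])
      selections[[r]] <- if (selection_scope == "full-cohort") {
        cfg_r <- rls_config(lambda = lam_r, lambda_grid = config$lambda_grid,
                            intercept = config$intercept)
        greedy_rls_select(D, ypm, cfg_r, select_k)$ordered_features
      } else {
        sort(unique(unlist(fold_sel_r)))
      }
    }
  }
  structure(
    list(
      model_spec = model_spec,
      feature_names = colnames(D),
      scores = scores,
      full_scores = full_scores,
      folds = folds_mat,
      lambdas = lambdas_mat,
      modal_lambda = apply(lambdas_mat, 2, modal_value),
      auc = apply(scores, 2, auc, labels = y01),
      auc_full = if (!is.null(select_k)) apply(full_scores, 2, auc, labels = y01),
      selections = selections,
      fold_selections = fold_selections,
      outcome = y01,
      select_k = select_k,
      selection_scope = if (!is.null(select_k)) selection_scope,
      plan = plan
    ),
    class = "nested_cv_result"
  )
}

#' @export
print.nested_cv_result <- function(x, ...) {
  ci <- mean_auc_ci(if (length(x$auc) > 1) x$auc else rep(x$auc, 2))
  cat(sprintf("nested_cv_result [%s]: %d repetitions, mean AUC %.3f (95%% CI %.3f, %.3f)\n",
              x$model_spec, length(x$auc), ci["mean"], ci["ci_low"], ci["ci_high"]))
  if (!is.null(x$selections)) {
    cat(sprintf("  selection: %d features per repetition (%s scope)\n",
                x$select_k, x$selection_scope))
  }
  invisible(x)
}

#' Union biomarker panel across repetitions
#'
#' Deduplicated union of the per-repetition selected feature lists, with each
#' feature's selection frequency (fraction of repetitions containing it),
#' sorted by frequency then name.
#'
#' @param results a [nested_cv()] result with selection enabled.
#' @return object of class `marker_panel`: `union` data.frame (feature,
#'   frequency) and the per-repetition lists.
#' @export
panel_union <- function(results) {
  if (is.null(results$selections)) stopf("selection was not enabled in this nested_cv run")
  R <- length(results$selections)
  feats <- sort(unique(unlist(results$selections)))
  freq <- vapply(feats, function(f) {
    mean(vapply(results$selections, function(s) f %in% s, logical(1)))
  }, numeric(1))
  ord <- order(-freq, feats)
  structure(
    list(
      union = data.frame(feature = feats[ord], frequency = unname(freq[ord]),
                         stringsAsFactors = FALSE),
      per_repetition = results$selections,
      repetitions = R
    ),
    class = "marker_panel"
  )
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d features from %d repetitions\n",
              nrow(x$union), x$repetitions))
  print(utils::head(x$union, 10), row.names = FALSE)
  invisible(x)
}

#' External-cohort validation by averaged model transfer
#'
#' Per repetition, the regularisation parameter is chosen by stratified inner
#' cross-validation on the full training cohort and one model is fitted on all
#' training samples (restricted to `feature_set` plus `covariate_set`); the
#' repetition-wise weight vectors and intercepts are then averaged into a
#' single linear model which scores the validation cohort once.
#'
#' @param train,valid preprocessed [cohort_table()]s; `valid` must contain all
#'   model columns.
#' @param feature_set metabolite features (must be measured in `valid`).
#' @param config an [rls_config()].
#' @param plan a [cv_plan()]; `inner_folds` and `repetitions` are used.
#' @param covariate_set clinical covariates included in the model.
#' @return object of class `external_validation_result`: validation `scores`,
#'   the averaged `model`, per-repetition `lambdas`, and the validation
#'   outcome.
#' @export
external_validation <- function(train, valid, feature_set, config = rls_config(),
                                plan = cv_plan(), covariate_set = character()) {
  missing_f <- setdiff(feature_set, colnames(valid$features))
  if (length(missing_f)) {
    stopf("feature(s) not measured in the validation cohort: %s",
          paste(missing_f, collapse = ", "))
  }
  D_tr <- build_model_matrix(train, feature_set, covariate_set)
  D_va <- build_model_matrix(valid, feature_set, covariate_set)
  D_va <- D_va[, colnames(D_tr), drop = FALSE]
  y01 <- train$outcome
  ypm <- y01 * 2 - 1
  R <- plan$repetitions
  W <- matrix(0, ncol(D_tr), R, dimnames = list(colnames(D_tr), NULL))
  b <- numeric(R)
  lambdas <- numeric(R)
  for (r in seq_len(R)) {
    lam <- choose_lambda(D_tr, NULL, y01, seq_along(y01), plan$inner_folds,
                         config$lambda_grid, config$intercept, plan$seed + r)
    lambdas[r] <- lam
    m <- fit_rls(D_tr, ypm, rls_config(lambda = lam, lambda_grid = config$lambda_grid,
                                       intercept = config$intercept))
    W[, r] <- m$weights
    b[r] <- m$intercept_value
  }
  w_bar <- rowMeans(W)
  b_bar <- mean(b)
  train_scores <- drop(D_tr %*% w_bar) + b_bar
  model <- structure(
    list(
      feature_names = colnames(D_tr),
      weights = stats::setNames(w_bar, colnames(D_tr)),
      intercept_value = b_bar,
      lambda = modal_value(lambdas),
      train_score_sd = sd1(train_scores),
      degenerate_scores = sd1(train_scores) <= 0
    ),
    class = "rls_model"
  )
  structure(
    list(
      scores = predict(model, D_va),
      model = model,
      lambdas = lambdas,
      outcome = valid$outcome
    ),
    class = "external_validation_result"
  )
}
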