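# Regularised least-squares (ridge) binary risk classification with
# closed-form leave-one-out and greedy forward feature selection.
#
# Throughout, the model with an intercept is fit by centring the feature
# columns and the labels and back-solving the intercept, which is equivalent
# to an unpenalised intercept column. All leave-one-out quantities come from
# the regularised hat matrix H = J/n + Xc (Xc'Xc + lambda I)^-1 Xc' (the J/n
# term only with an intercept): loo_i = (yhat_i - H_ii y_i) / (1 - H_ii).

#' RLS configuration
#'
#' @param lambda regularisation strength (>= 0) used by fixed-lambda fits and
#'   greedy selection.
#' @param lambda_grid positive, strictly increasing grid for selection by
#'   inner cross-validation; defaults to powers of 2 from 2^-15 to 2^15.
#' @param intercept fit an unpenalised intercept (default TRUE; cohorts are
#'   class-imbalanced, so a bias term matters).
#' @return object of class `rls_config`.
#' @export
rls_config <- function(lambda = 1, lambda_grid = 2^(-15:15), intercept = TRUE) {
  if (lambda < 0) stopf("lambda must be >= 0")
  if (length(lambda_grid) == 0L || any(lambda_grid <= 0) || is.unsorted(lambda_grid, strictly = TRUE)) {
    stopf("lambda_grid must be non-empty, strictly positive and increasing")
  }
  structure(list(lambda = lambda, lambda_grid = lambda_grid, intercept = isTRUE(intercept)),
            class = "rls_config")
}

# Centre X (columns) and y when an intercept is requested; returns the pieces
# every solver needs.
centre_xy <- function(X, y, intercept) {
  if (intercept) {
    mu <- colMeans(X)
    ybar <- mean(y)
    list(Xc = sweep(X, 2, mu, "-"), yc = y - ybar, mu = mu, ybar = ybar)
  } else {
    list(Xc = X, yc = y, mu = rep(0, ncol(X)), ybar = 0)
  }
}

# Ridge weights on (already centred) data; primal or dual by problem shape.
ridge_weights <- function(Xc, yc, lambda, force = c("auto", "primal", "dual")) {
  force <- match.arg(force)
  n <- nrow(Xc)
  p <- ncol(Xc)
  use_primal <- switch(force, auto = p <= n, primal = TRUE, dual = FALSE)
  sol <- function(M, b) {
    tryCatch(solve(M, b), error = function(e) {
      stopf("singular RLS system (collinear features at lambda = %g); use lambda > 0", lambda)
    })
  }
  if (use_primal) {
    drop(sol(crossprod(Xc) + diag(lambda, p), crossprod(Xc, yc)))
  } else {
    drop(crossprod(Xc, sol(tcrossprod(Xc) + diag(lambda, n), yc)))
  }
}

#' Fit a regularised least-squares risk classifier
#'
#' Minimises `sum((y - X w - b)^2) + lambda * ||w||^2` with labels encoded
#' +1 (progressor) / -1 (non-progressor); 0/1 outcomes are re-coded
#' automatically. The primal (features <= samples) or dual (features >
#' samples) formulation is chosen automatically; both give identical weights.
#'
#' @param X numeric matrix (samples x features) with column names, no missing
#'   values.
#' @param y outcome, +/-1 or 0/1, both classes present.
#' @param config an [rls_config()]; `config$lambda` is used.
#' @param formulation "auto" (default), or force "primal"/"dual".
#' @return object of class `rls_model`: `feature_names`, `weights`,
#'   `intercept_value`, `lambda`, `train_score_sd` and a `degenerate_scores`
#'   flag when all training scores coincide.
#' @export
fit_rls <- function(X, y, config = rls_config(), formulation = "auto") {
  X <- as.matrix(X)
  if (anyNA(X)) stopf("X contains missing values")
  y <- as_pm1(y)
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  cc <- centre_xy(X, y, config$intercept)
  w <- ridge_weights(cc$Xc, cc$yc, config$lambda, formulation)
  intercept <- cc$ybar - sum(cc$mu * w)
  scores <- drop(X %*% w) + intercept
  ssd <- sd1(scores)
  structure(
    list(
      feature_names = colnames(X),
      weights = stats::setNames(w, colnames(X)),
      intercept_value = intercept,
      lambda = config$lambda,
      train_score_sd = ssd,
      degenerate_scores = !is.finite(ssd) || ssd <= 0
    ),
    class = "rls_model"
  )
}

#' Predict risk scores from an RLS model
#'
#' @param object an `rls_model`.
#' @param X matrix whose columns (by name) match the model's features; order
#'   may differ.
#' @param ... unused.
#' @return numeric risk-score vector (higher = higher predicted risk).
#' @export
predict.rls_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stopf("X must have column names matching the model features")
  missing <- setdiff(object$feature_names, colnames(X))
  extra <- setdiff(colnames(X), object$feature_names)
  if (length(missing) || length(extra)) {
    stopf("feature mismatch; missing: [%s], extra: [%s]",
          paste(missing, collapse = ", "), paste(extra, collapse = ", "))
  }
  drop(X[, object$feature_names, drop = FALSE] %*% object$weights) + object$intercept_value
}

#' @export
print.rls_model <- function(x, ...) {
  cat(sprintf("rls_model: %d features, lambda = %g, intercept = %.4g, train score SD = %.4g\n",
              length(x$weights), x$lambda, x$intercept_value, x$train_score_sd))
  invisible(x)
}

# Hat diagonal and fitted values for a fixed lambda; used by loo_predictions.
hat_and_fit <- function(X, y, lambda, intercept) {
  n <- nrow(X)
  p <- ncol(X)
  cc <- centre_xy(X, y, intercept)
  if (p <= n) {
    M <- tryCatch(solve(crossprod(cc$Xc) + diag(lambda, p)),
                  error = function(e) stopf("singular system; use lambda > 0"))
    XM <- cc$Xc %*% M
    h <- rowSums(XM * cc$Xc)
    yhat <- drop(XM %*% crossprod(cc$Xc, cc$yc))
  } else {
    K <- tcrossprod(cc$Xc)
    A <- tryCatch(solve(K + diag(lambda, n)),
                  error = function(e) stopf("singular system; use lambda > 0"))
    KA <- K %*% A
    h <- rowSums(K * A) # diag(K A), A symmetric
    yhat <- drop(KA %*% cc$yc)
  }
  if (intercept) {
    h <- h + 1 / n
    yhat <- yhat + cc$ybar
  }
  list(h = h, yhat = yhat)
}

#' Closed-form leave-one-out predictions for RLS
#'
#' Returns, for every sample, the prediction of the model trained on all other
#' samples, computed from the regularised hat matrix without retraining:
#' `loo_i = (yhat_i - H_ii y_i) / (1 - H_ii)`. Agrees with explicit
#' retraining to numerical precision.
#'
#' @inheritParams fit_rls
#' @return numeric vector of leave-one-out risk scores.
#' @export
loo_predictions <- function(X, y, config = rls_config()) {
  X <- as.matrix(X)
  y <- as_pm1(y)
  if (nrow(X) < 3L) stopf("need at least 3 samples")
  hf <- hat_and_fit(X, y, config$lambda, config$intercept)
  if (any(hf$h >= 1 - 1e-10)) {
    stopf("leverage H_ii >= 1: system is ill-conditioned; increase lambda")
  }
  (hf$yhat - hf$h * y) / (1 - hf$h)
}

#' Greedy forward feature selection for RLS (GreedyRLS)
#'
#' Starting from the empty set, repeatedly adds the feature that minimises the
#' leave-one-out mean squared error of the RLS model on the augmented set, at
#' fixed `config$lambda`. Ties are broken by the lowest column index. The
#' implementation updates the hat matrix incrementally through the Schur
#' complement of each added column, and is algebraically identical to naively
#' refitting and recomputing the closed-form LOO for every candidate at every
#' step.
#'
#' @inheritParams fit_rls
#' @param k number of features to select (1 <= k <= ncol(X)).
#' @return object of class `greedy_selection`: `ordered_features` (selection
#'   order), `criterion_path` (LOO MSE after each addition), `lambda`.
#' @export
greedy_rls_select <- function(X, y, config = rls_config(), k) {
  X <- as.matrix(X)
  y <- as_pm1(y)
  n <- nrow(X)
  p <- ncol(X)
  if (k < 1L || k > p) stopf("k must be in [1, %d]", p)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  lambda <- config$lambda
  if (lambda < 0) stopf("lambda must be >= 0")
  cc <- centre_xy(X, y, config$intercept)
  R <- cc$Xc                       # residual columns (I - H_S) x_f
  s <- colSums(R * cc$Xc) + lambda # Schur complements lambda + x_f' (I - H_S) x_f
  h <- rep(if (config$intercept) 1 / n else 0, n)
  yhat_c <- rep(0, n)              # H_S y on the centred scale
  selected <- integer(0)
  crit <- numeric(0)
  for (step in seq_len(k)) {
    u <- drop(crossprod(R, cc$yc)) # r_f' y
    num <- cc$ybar + yhat_c + sweep_cols(R, u / pmax(s, 1e-300))
    hm <- h + sweep_cols(R * R, 1 / pmax(s, 1e-300))
    denom <- 1 - hm
    L <- (num - hm * y) / denom
    mse <- colMeans((y - L)^2)
    mse[selected] <- Inf
    mse[!is.finite(mse)] <- Inf
    mse[colSums(denom <= 1e-10) > 0] <- Inf # candidate drives a leverage to 1
    j <- which.min(mse)
    if (!is.finite(mse[j])) stopf("no admissible candidate at step %d; increase lambda", step)
    rj <- R[, j]
    sj <- s[j]
    t_vec <- drop(crossprod(cc$Xc, rj))
    h <- h + rj^2 / sj
    yhat_c <- yhat_c + rj * (sum(rj * cc$yc) / sj)
    R <- R - outer(rj, t_vec / sj)
    s <- s - t_vec^2 / sj
    selected <- c(selected, j)
    crit <- c(crit, mse[j])
  }
  structure(
    list(
      ordered_features = colnames(X)[selected],
      criterion_path = crit,
      lambda = lambda
    ),
    class = "greedy_selection"
  )
}

# columnwise scale helper: M * rep(row vector w), i.e. M %*% diag(w), without
# building the diagonal.
sweep_cols <- function(M, w) M * rep(w, each = nrow(M))

#' @export
print.greedy_selection <- function(x, ...) {
  cat(sprintf("greedy_selection (lambda = %g): %s\n", x$lambda,
              paste(x$ordered_features, collapse = " > ")))
  invisible(x)
}

#' Cross-validated AUC as a function of panel size
#'
#' For k = 1..k_max, estimates the out-of-fold AUC of the k-feature greedy
#' panel; selection is repeated inside every training fold, so the curve is
#' honest about selection. Reports the AUC curve and the smallest k whose
#' mean AUC is within one standard error (over repetitions) of the maximum.
#'
#' @inheritParams fit_rls
#' @param k_max largest panel size to evaluate.
#' @param cv_plan a [cv_plan()]; `outer_folds` and `repetitions` are used.
#' @return list with `auc_by_k` (data.frame k / mean_auc / se) and `best_k`.
#' @export
sweep_panel_size <- function(X, y, config = rls_config(), k_max, cv_plan = cv_plan()) {
  X <- as.matrix(X)
  y01 <- as_01(y)
  if (k_max < 1L || k_max > ncol(X)) stopf("k_max must be in [1, %d]", ncol(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  reps <- cv_plan$repetitions
  auc_mat <- matrix(NA_real_, reps, k_max)
  for (r in seq_len(reps)) {
    folds <- stratified_folds(y01, cv_plan$outer_folds, seed = cv_plan$seed + r)
    scores <- matrix(NA_real_, length(y01), k_max)
    for (f in seq_len(cv_plan$outer_folds)) {
      tr <- folds != f
      sel <- greedy_rls_select(X[tr, , drop = FALSE], y01[tr], config, k_max)
      for (k in seq_len(k_max)) {
        feats <- sel$ordered_features[seq_len(k)]
        m <- fit_rls(X[tr, feats, drop = FALSE], y01[tr], config)
        scores[!tr, k] <- predict(m, X[!tr, feats, drop = FALSE])
      }
    }
    auc_mat[r, ] <- apply(scores, 2, auc, labels = y01)
  }
  mean_auc <- colMeans(auc_mat)
  se <- apply(auc_mat, 2, function(a) if (reps > 1) sd1(a) / sqrt(reps) else 0)
  kmax_at <- which.max(mean_auc)
  best_k <- min(which(mean_auc >= mean_auc[kmax_at] - se[kmax_at]))
  list(
    auc_by_k = data.frame(k = seq_len(k_max), mean_auc = mean_auc, se = se),
    best_k = best_k
  )
}

# ---- lambda-path scoring helpers (shared with the CV harness) --------------

# Scores of ridge models over a lambda grid for one train/test split, primal
# (eigen of X'X) route; exact for any shape but cheapest when p is small.
lambda_scores_primal <- function(X, y, tr, te, lambdas, intercept) {
  cc <- centre_xy(X[tr, , drop = FALSE], y[tr], intercept)
  E <- eigen(crossprod(cc$Xc), symmetric = TRUE)
  d <- pmax(E$values, 0)
  b <- drop(crossprod(E$vectors, crossprod(cc$Xc, cc$yc)))
  A <- sweep(X[te, , drop = FALSE], 2, cc$mu, "-") %*% E$vectors
  out <- vapply(lambdas, function(l) drop(A %*% (b / (d + l))) + cc$ybar,
                numeric(length(te)))
  matrix(out, nrow = length(te))
}

# Same, dual route from a precomputed Gram matrix K = X X'; used when the
# feature count exceeds the fold size (e.g. full-metabolome models).
lambda_scores_kernel <- function(K, y, tr, te, lambdas, intercept) {
  Ktr <- K[tr, tr, drop = FALSE]
  Kte <- K[te, tr, drop = FALSE]
  n <- length(tr)
  if (intercept) {
    rm_tr <- rowMeans(Ktr)
    gm <- mean(Ktr)
    Ktr <- Ktr - outer(rm_tr, rep(1, n)) - outer(rep(1, n), rm_tr) + gm
    Kte <- Kte - outer(rowMeans(Kte), rep(1, n)) - outer(rep(1, length(te)), rm_tr) + gm
    ybar <- mean(y[tr])
  } else {
    ybar <- 0
  }
  yc <- y[tr] - ybar
  E <- eigen(Ktr, symmetric = TRUE)
  e <- pmax(E$values, 0)
  b <- drop(crossprod(E$vectors, yc))
  A <- Kte %*% E$vectors
  out <- vapply(lambdas, function(l) drop(A %*% (b / (e + l))) + ybar,
                numeric(length(te)))
  matrix(out, nrow = length(te))
}
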