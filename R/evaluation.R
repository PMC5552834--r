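# Discrimination statistics: ROC/AUC, DeLong's test for correlated ROC
# curves, risk-probability conversion, discrimination slope and IDI.

#' Area under the ROC curve
#'
#' Mann-Whitney estimator: the probability that a random progressor's score
#' exceeds a random non-progressor's, ties counted one half. Equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome (0/1 or -1/+1), both classes present.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  y <- as_01(labels)
  if (length(scores) != length(y)) stopf("scores and labels differ in length")
  if (anyNA(scores)) stopf("scores contain missing values")
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  if (npos == 0L || nneg == 0L) stopf("both classes must be present")
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Empirical ROC curve
#'
#' @inheritParams auc
#' @return object of class `roc_result`: data.frame of (threshold, fpr, tpr)
#'   points from (0,0) to (1,1), and the trapezoidal `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_01(labels)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  keep <- c(diff(ss) != 0, TRUE) # collapse tied thresholds
  tpr <- c(0, cumsum(ys)[keep] / sum(y == 1))
  fpr <- c(0, cumsum(1 - ys)[keep] / sum(y == 0))
  thr <- c(Inf, ss[keep])
  a <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = a),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d points)\n", x$auc, nrow(x$points)))
  invisible(x)
}

#' Mean AUC with empirical percentile confidence interval
#'
#' Summarises the AUC values of repeated cross-validation runs by their
#' arithmetic mean and the 2.5th / 97.5th empirical percentiles (linear
#' interpolation).
#'
#' @param auc_values numeric vector (length >= 2).
#' @return named vector: mean, ci_low, ci_high.
#' @export
mean_auc_ci <- function(auc_values) {
  if (length(auc_values) < 2L) stopf("need at least two AUC values")
  q <- stats::quantile(auc_values, c(0.025, 0.975), names = FALSE, type = 7)
  c(mean = mean(auc_values), ci_low = q[1], ci_high = q[2])
}

# DeLong structural components: V10 (per positive, mean over negatives of
# [pos > neg] + 1/2 [tie]) and V01 (per negative, symmetric).
delong_components <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong's test for two correlated ROC curves
#'
#' Compares the AUCs of two models scored on the same samples, using the
#' covariance of the structural components of the Mann-Whitney statistics.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels binary outcome shared by both models.
#' @return object of class `delong_comparison`: `auc_a`, `auc_b`,
#'   `var_diff`, `z`, `p_value` (two-sided normal).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_01(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    stopf("scores must be paired with labels")
  }
  m <- sum(y == 1)
  n <- sum(y == 0)
  if (m == 0L || n == 0L) stopf("both classes must be present")
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  dauc <- ca$auc - cb$auc
  if (var_diff <= 0) {
    if (abs(dauc) < 1e-12) {
      z <- 0
      p <- 1
      var_diff <- max(var_diff, 0)
    } else {
      stopf("zero variance of the AUC difference with unequal AUCs")
    }
  } else {
    z <- dauc / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(auc_a = ca$auc, auc_b = cb$auc, var_diff = var_diff, z = z, p_value = p),
    class = "delong_comparison"
  )
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.4f vs %.4f, z = %.3f, p = %.3g\n",
              x$auc_a, x$auc_b, x$z, x$p_value))
  invisible(x)
}

#' DeLong confidence interval for a single AUC
#'
#' @inheritParams auc
#' @param level confidence level (default 0.95).
#' @return named vector auc, ci_low, ci_high (truncated to [0, 1]).
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  y <- as_01(labels)
  m <- sum(y == 1)
  n <- sum(y == 0)
  if (m == 0L || n == 0L) stopf("both classes must be present")
  comp <- delong_components(scores, y)
  v <- stats::var(comp$v10) / m + stats::var(comp$v01) / n
  zq <- stats::qnorm(1 - (1 - level) / 2)
  half <- zq * sqrt(max(v, 0))
  c(auc = comp$auc,
    ci_low = max(0, comp$auc - half),
    ci_high = min(1, comp$auc + half))
}

#' Convert RLS risk scores to risk probabilities
#'
#' Scales the scores by the training-score SD and applies the logistic
#' (inverse-logit) map `p = 1 / (1 + exp(-score / sd))`. The map is strictly
#' increasing, so AUC is invariant under it.
#'
#' @param scores numeric risk scores.
#' @param score_sd positive scale, normally the `train_score_sd` stored in the
#'   fitted model (kept fixed across cohorts).
#' @return vector of probabilities in (0, 1).
#' @export
risk_probabilities <- function(scores, score_sd) {
  if (!is.numeric(score_sd) || length(score_sd) != 1L || !is.finite(score_sd) || score_sd <= 0) {
    stopf("score_sd must be a single positive number")
  }
  stats::plogis(scores / score_sd)
}

#' Discrimination slope
#'
#' Mean predicted risk probability among progressors minus that among
#' non-progressors.
#'
#' @param probabilities predicted risk probabilities.
#' @param labels binary outcome.
#' @return the discrimination slope (DS).
#' @export
discrimination_slope <- function(probabilities, labels) {
  y <- as_01(labels)
  if (sum(y == 1) == 0L || sum(y == 0) == 0L) stopf("both classes must be present")
  mean(probabilities[y == 1]) - mean(probabilities[y == 0])
}

#' Integrated discrimination improvement as percentage of the reference DS
#'
#' `100 * (ds_new - ds_old) / ds_old`: the relative improvement in
#' discrimination slope obtained by adding new predictors.
#'
#' @param ds_new,ds_old discrimination slopes of the extended and reference
#'   models; `ds_old` must be non-zero.
#' @return IDI in percent.
#' @export
idi <- function(ds_new, ds_old) {
  if (ds_old == 0) stopf("reference discrimination slope is zero")
  100 * (ds_new - ds_old) / ds_old
}

#' Numerical check of the IDI / integrated-NRI equivalence
#'
#' The absolute IDI (difference of discrimination slopes) equals the integral
#' over all probability cut-offs of the continuous net reclassification
#' improvement NRI(c) = (sensitivity gain at c) - (false-positive-rate gain
#' at c). This computes both sides, the integral by a midpoint rule on a
#' uniform cut-off grid.
#'
#' @param probabilities_old,probabilities_new paired risk probabilities.
#' @param labels binary outcome.
#' @param grid_size number of cut-offs (default 1e4).
#' @return list with `idi_direct` and `nri_integral`.
#' @export
idi_nri_equivalence_check <- function(probabilities_old, probabilities_new, labels,
                                      grid_size = 1e4) {
  y <- as_01(labels)
  idi_direct <- discrimination_slope(probabilities_new, y) -
    discrimination_slope(probabilities_old, y)
  grid <- (seq_len(grid_size) - 0.5) / grid_size
  surv <- function(p, cls) {
    f <- stats::ecdf(p[y == cls])
    1 - f(grid) # P(p > c) on the grid
  }
  d_tpr <- surv(probabilities_new, 1) - surv(probabilities_old, 1)
  d_fpr <- surv(probabilities_new, 0) - surv(probabilities_old, 0)
  list(idi_direct = idi_direct, nri_integral = mean(d_tpr - d_fpr))
}
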