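# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately take different computational routes than the package.

# Null-cohort configuration (no planted effects, no marker correlations).
null_cohort_config <- function(seed, n_samples = 543L, n_progressors = 146L,
                               n_targeted = 26L, n_untargeted = 542L, ...) {
  synthetic_config(
    n_samples = n_samples, n_progressors = n_progressors,
    n_targeted = n_targeted, n_untargeted = n_untargeted,
    planted_effects = data.frame(feature = character(), log_or = numeric()),
    marker_correlations = data.frame(a = character(), b = character(), rho = numeric()),
    seed = seed, ...
  )
}

# Small single-marker configuration for parameter-recovery simulations; the
# latent (missingness-free) scale is used so the check targets the logistic
# fit, not the imputation distortion.
single_marker_config <- function(seed, log_or, n_samples = 2000L,
                                 n_progressors = round(0.269 * n_samples)) {
  synthetic_config(
    n_samples = n_samples, n_progressors = n_progressors,
    n_targeted = 2L, n_untargeted = 2L,
    planted_effects = data.frame(feature = "glucose", log_or = log_or),
    marker_correlations = data.frame(a = character(), b = character(), rho = numeric()),
    missing_rate = 0, seed = seed
  )
}

# Brute-force AUC: count over all positive x negative pairs, ties as 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Ridge fit via the augmented-design route (unpenalised intercept as an
# explicit column with a zero penalty entry) -- a different construction from
# the package's centring route.
ridge_aug <- function(X, y, lambda, intercept = TRUE) {
  Xa <- if (intercept) cbind(1, X) else X
  P <- diag(rep(lambda, ncol(Xa)), nrow = ncol(Xa))
  if (intercept) P[1, 1] <- 0
  solve(crossprod(Xa) + P, crossprod(Xa, y))
}

# Leave-one-out scores by explicit retraining (n separate fits).
brute_loo <- function(X, y, lambda, intercept = TRUE) {
  vapply(seq_len(nrow(X)), function(i) {
    b <- ridge_aug(X[-i, , drop = FALSE], y[-i], lambda, intercept)
    xi <- if (intercept) c(1, X[i, ]) else X[i, ]
    sum(xi * b)
  }, numeric(1))
}

# Closed-form LOO via an explicitly built dense hat matrix of the augmented
# design (independent of the package's centring/eigen path).
hat_loo <- function(X, y, lambda, intercept = TRUE) {
  Xa <- if (intercept) cbind(1, X) else X
  P <- diag(rep(lambda, ncol(Xa)), nrow = ncol(Xa))
  if (intercept) P[1, 1] <- 0
  H <- Xa %*% solve(crossprod(Xa) + P, t(Xa))
  yhat <- drop(H %*% y)
  (yhat - diag(H) * y) / (1 - diag(H))
}

# Naive GreedyRLS: at every step refit and recompute the LOO error for every
# candidate from scratch via the dense hat-matrix route.
naive_greedy <- function(X, y, lambda, k, intercept = TRUE) {
  sel <- integer(0)
  for (s in seq_len(k)) {
    cand <- setdiff(seq_len(ncol(X)), sel)
    mses <- vapply(cand, function(j) {
      loo <- hat_loo(X[, c(sel, j), drop = FALSE], y, lambda, intercept)
      mean((y - loo)^2)
    }, numeric(1))
    sel <- c(sel, cand[which.min(mses)])
  }
  colnames(X)[sel]
}

# DeLong variance of an AUC difference from first principles (explicit
# structural components and their sample covariances).
brute_delong_var <- function(sa, sb, y) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  psi <- function(s) outer(s[pos], s[neg], function(a, b) (a > b) + 0.5 * (a == b))
  pa <- psi(sa)
  pb <- psi(sb)
  v10 <- cbind(rowMeans(pa), rowMeans(pb))
  v01 <- cbind(colMeans(pa), colMeans(pb))
  S <- cov(v10) / length(pos) + cov(v01) / length(neg)
  S[1, 1] + S[2, 2] - 2 * S[1, 2]
}

# Random RLS test instance.
random_instance <- function(seed, n, p, signal = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", seq_len(p))))
  beta <- c(rep(signal, min(3, p)), rep(0, max(0, p - 3)))
  y <- sign(drop(X %*% beta) + rnorm(n))
  y[y == 0] <- 1
  list(X = X, y = y)
}
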