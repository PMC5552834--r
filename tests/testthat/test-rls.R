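# RLS core: fitting, prediction, closed-form leave-one-out, greedy selection,
# panel-size sweep.

test_that("hand-computable fits and limits are exact", {
  m <- fit_rls(matrix(c(1, -1), ncol = 1, dimnames = list(NULL, "x")),
               c(1, -1), rls_config(lambda = 1, intercept = FALSE))
  expect_equal(unname(m$weights), 2 / 3)
  # huge lambda: weights vanish, scores collapse to the intercept (class mean)
  inst <- random_instance(1, 40, 6)
  big <- fit_rls(inst$X, inst$y, rls_config(lambda = 1e8))
  expect_lt(max(abs(big$weights)), 1e-5)
  expect_lt(max(abs(predict(big, inst$X) - mean(inst$y))), 1e-4)
  expect_true(big$degenerate_scores || big$train_score_sd > 0)
  expect_error(rls_config(lambda = -1), "lambda")
  expect_error(rls_config(lambda_grid = c(2, 1)), "grid")
})

test_that("primal and dual solutions coincide", {
  for (s in 1:5) {
    inst <- random_instance(s, 50, 500)
    for (ic in c(TRUE, FALSE)) {
      cfg <- rls_config(lambda = 2^(s - 3), intercept = ic)
      wp <- fit_rls(inst$X, inst$y, cfg, formulation = "primal")$weights
      wd <- fit_rls(inst$X, inst$y, cfg, formulation = "dual")$weights
      expect_lt(max(abs(wp - wd)), 1e-8)
    }
  }
})

test_that("prediction aligns columns by name and reports training score SD", {
  inst <- random_instance(2, 30, 5)
  m <- fit_rls(inst$X, inst$y, rls_config(lambda = 0.5))
  sc <- predict(m, inst$X)
  expect_equal(sd(sc), m$train_score_sd)
  perm <- inst$X[, c(3, 1, 5, 2, 4)]
  expect_equal(predict(m, perm), sc)
  expect_error(predict(m, inst$X[, 1:3]), "missing")
  expect_error(predict(m, cbind(inst$X, zz = rnorm(30))), "extra")
  z <- fit_rls(inst$X, inst$y, rls_config(lambda = 1e12))
  expect_lt(diff(range(predict(z, inst$X))), 1e-6) # ~zero weights: constant scores
})

test_that("closed-form LOO equals explicit retraining and the augmented-hat oracle", {
  for (s in 1:6) {
    n <- sample(10:40, 1)
    p <- sample(2:8, 1)
    inst <- random_instance(s + 100, n, p)
    ic <- s %% 2 == 0
    lam <- 2^(s - 3)
    loo <- loo_predictions(inst$X, inst$y, rls_config(lambda = lam, intercept = ic))
    expect_lt(max(abs(loo - brute_loo(inst$X, inst$y, lam, ic))), 1e-8)
    expect_lt(max(abs(loo - hat_loo(inst$X, inst$y, lam, ic))), 1e-8)
  }
  # lambda = 0, y equal to the single feature: perfect fit, zero LOO residuals
  x <- rnorm(12)
  loo0 <- loo_predictions(matrix(x, dimnames = list(NULL, "x")), x,
                          rls_config(lambda = 0, intercept = FALSE))
  expect_lt(max(abs(loo0 - x)), 1e-10)
  expect_error(loo_predictions(matrix(rnorm(2), dimnames = list(NULL, "x")),
                               c(1, -1), rls_config()), "3 samples")
})

test_that("greedy selection matches the naive refit-everything oracle", {
  for (s in 1:3) {
    inst <- random_instance(s + 50, 45, 60, signal = 0.9)
    ic <- s != 2
    g <- greedy_rls_select(inst$X, inst$y, rls_config(lambda = 1.5, intercept = ic), 4)
    expect_identical(g$ordered_features, naive_greedy(inst$X, inst$y, 1.5, 4, ic))
    expect_equal(length(g$criterion_path), 4L)
  }
  # k = 1 equals exhaustive single-feature search
  inst <- random_instance(9, 60, 30, signal = 0.8)
  g1 <- greedy_rls_select(inst$X, inst$y, rls_config(lambda = 1), 1)
  mses <- vapply(seq_len(30), function(j) {
    mean((inst$y - hat_loo(inst$X[, j, drop = FALSE], inst$y, 1))^2)
  }, numeric(1))
  expect_identical(g1$ordered_features, colnames(inst$X)[which.min(mses)])
  expect_error(greedy_rls_select(inst$X, inst$y, rls_config(), 31), "k must be")
})

test_that("greedy ties break to the lowest column index", {
  set.seed(5)
  X <- matrix(rnorm(80 * 6), 80)
  X <- cbind(X[, 1:2], X[, 2], X[, 3:6]) # duplicate informative column 2 at index 3
  colnames(X) <- paste0("f", 1:7)
  y <- sign(X[, 2] + 0.5 * rnorm(80))
  g <- greedy_rls_select(X, y, rls_config(lambda = 1), 1)
  expect_identical(g$ordered_features, "f2")
})

test_that("greedy finds a planted marker first and training error decreases along the path", {
  first <- vapply(1:20, function(s) {
    set.seed(s)
    X <- matrix(rnorm(500 * 100), 500, dimnames = list(NULL, paste0("f", 1:100)))
    lp <- log(2.2) * X[, 37]
    y <- ifelse(runif(500) < plogis(-1 + lp), 1, -1)
    greedy_rls_select(X, y, rls_config(lambda = 1), 1)$ordered_features
  }, character(1))
  expect_gte(sum(first == "f37"), 18)
  # monotone training MSE along a greedy path
  inst <- random_instance(77, 100, 30, signal = 0.6)
  g <- greedy_rls_select(inst$X, inst$y, rls_config(lambda = 1), 8)
  tr_mse <- vapply(seq_along(g$ordered_features), function(k) {
    m <- fit_rls(inst$X[, g$ordered_features[1:k], drop = FALSE], inst$y, rls_config(lambda = 1))
    mean((inst$y - predict(m, inst$X[, g$ordered_features[1:k], drop = FALSE]))^2)
  }, numeric(1))
  expect_true(all(diff(tr_mse) <= 1e-10))
})

test_that("panel-size sweep plateaus near the planted panel size and is flat on noise", {
  set.seed(11)
  n <- 400
  X <- matrix(rnorm(n * 40), n, dimnames = list(NULL, paste0("f", 1:40)))
  lp <- drop(X[, 1:5] %*% rep(0.8, 5))
  y <- as.integer(runif(n) < plogis(-1 + lp))
  sw <- sweep_panel_size(X, y, rls_config(lambda = 4), k_max = 10,
                         cv_plan(outer_folds = 5, repetitions = 3, seed = 2))
  expect_equal(nrow(sw$auc_by_k), 10L)
  expect_gte(sw$best_k, 3)
  expect_lte(sw$best_k, 7)
  expect_gt(max(sw$auc_by_k$mean_auc), 0.75)
  # pure noise: AUC stays near 1/2 everywhere
  y0 <- sample(y)
  sw0 <- sweep_panel_size(X, y0, rls_config(lambda = 4), k_max = 5,
                          cv_plan(outer_folds = 5, repetitions = 3, seed = 3))
  expect_true(all(abs(sw0$auc_by_k$mean_auc - 0.5) < 0.12))
  sw1 <- sweep_panel_size(X, y, rls_config(lambda = 4), k_max = 1,
                          cv_plan(outer_folds = 5, repetitions = 2, seed = 4))
  expect_equal(nrow(sw1$auc_by_k), 1L)
})
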