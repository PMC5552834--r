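# Cross-validation harness: stratification, nesting, determinism, leakage,
# panel union, external transfer.

test_that("stratified folds balance both classes and partition the cohort", {
  y <- rep(c(1, 0), c(146, 397))
  f <- stratified_folds(y, 10, seed = 3)
  pos_per_fold <- table(f[y == 1])
  neg_per_fold <- table(f[y == 0])
  expect_true(all(pos_per_fold %in% c(14, 15))) # 146 positives over 10 folds
  expect_true(all(neg_per_fold %in% c(39, 40)))
  expect_equal(sort(unique(f)), 1:10)
  expect_equal(length(f), 543L)
  expect_identical(f, stratified_folds(y, 10, seed = 3))
  expect_false(identical(f, stratified_folds(y, 10, seed = 4)))
  expect_error(stratified_folds(y, 147, seed = 1), "minority")
  expect_error(stratified_folds(rep(1, 5), 2), "both classes")
})

small_planted_table <- function(seed, n = 160, p_null = 18) {
  cfg <- synthetic_config(
    n_samples = n, n_progressors = round(0.3 * n), n_targeted = 2,
    n_untargeted = p_null + 2,
    planted_effects = data.frame(feature = c("glucose", "mannose"),
                                 log_or = c(log(2.5), log(2.0))),
    marker_correlations = data.frame(a = "glucose", b = "mannose", rho = 0.5),
    missing_rate = 0, seed = seed
  )
  standardise(generate_cohort(cfg))$table
}

test_that("nested CV is deterministic, aligned, and scores every sample once", {
  tab <- small_planted_table(1)
  plan <- cv_plan(4, 3, 2, seed = 9)
  cfg <- rls_config(lambda_grid = 2^seq(-3, 9, 3))
  r1 <- nested_cv(tab, colnames(tab$features), cfg, plan)
  r2 <- nested_cv(tab, colnames(tab$features), cfg, plan)
  expect_identical(r1$scores, r2$scores)
  expect_false(anyNA(r1$scores)) # every sample scored in every repetition
  expect_equal(dim(r1$scores), c(160L, 2L))
  expect_equal(length(r1$auc), 2L)
  expect_true(all(r1$lambdas %in% cfg$lambda_grid))
  # a planted two-marker cohort is predictable
  expect_gt(mean(r1$auc), 0.65)
})

test_that("no information leaks from test folds into training", {
  # canary: a feature equal to the outcome on fold-1 samples only (noise
  # elsewhere); with sound nesting the fold-1 model never sees it aligned
  # with its own test labels, so fold-1 test discrimination stays unremarkable
  cfg <- null_cohort_config(8, n_samples = 200, n_progressors = 60,
                            n_targeted = 2, n_untargeted = 18, missing_rate = 0)
  tab <- standardise(generate_cohort(cfg))$table
  plan <- cv_plan(4, 3, 1, seed = 21)
  folds <- stratified_folds(tab$outcome, 4, seed = plan$seed + 1)
  leak <- rnorm(200)
  leak[folds == 1] <- tab$outcome[folds == 1] * 2 - 1
  tab$features <- cbind(tab$features, canary = leak)
  tab$feature_meta <- rbind(tab$feature_meta,
                            data.frame(name = "canary", panel = "untargeted", identified = "no"))
  res <- nested_cv(tab, colnames(tab$features), rls_config(lambda_grid = 2^seq(-3, 9, 3)), plan)
  fold1 <- folds == 1
  expect_lt(auc(res$scores[fold1, 1], tab$outcome[fold1]), 0.75)
})

test_that("panel union aggregates selections with frequencies", {
  fake <- structure(list(selections = list(c("A", "B"), c("B", "C"))), class = "nested_cv_result")
  pu <- panel_union(fake)
  expect_equal(pu$union$feature, c("B", "A", "C"))
  expect_equal(pu$union$frequency, c(1, 0.5, 0.5))
  all_same <- structure(list(selections = rep(list(c("x1", "x2", "x3", "x4", "x5")), 4)),
                        class = "nested_cv_result")
  pu2 <- panel_union(all_same)
  expect_equal(nrow(pu2$union), 5L)
  expect_true(all(pu2$union$frequency == 1))
  expect_error(panel_union(structure(list(selections = NULL), class = "nested_cv_result")),
               "selection")
})

test_that("in-fold selection recovers planted markers and reports per-repetition lists", {
  tab <- small_planted_table(4)
  plan <- cv_plan(4, 3, 3, seed = 2)
  res <- nested_cv(tab, colnames(tab$features), rls_config(lambda_grid = 2^seq(-3, 9, 3)),
                   plan, select_k = 2)
  expect_equal(length(res$selections), 3L)
  expect_true(all(vapply(res$selections, length, integer(1)) == 2L))
  expect_equal(length(res$auc_full), 3L)
  pu <- panel_union(res)
  expect_true(all(c("glucose", "mannose") %in% pu$union$feature[1:3]))
  # fold-union scope reports the union of per-fold selections
  res2 <- nested_cv(tab, colnames(tab$features), rls_config(lambda_grid = 2^seq(-3, 9, 3)),
                    plan, select_k = 2, selection_scope = "fold-union")
  expect_true(all(vapply(res2$selections, length, integer(1)) >= 2L))
  expect_error(nested_cv(tab, colnames(tab$features), rls_config(), plan,
                         select_k = 2, covariate_set = "age"), "covariate_set")
})

test_that("modal lambda ties resolve to the smallest value", {
  expect_equal(rlspanel:::modal_value(c(1, 4, 4, 1)), 1)
  expect_equal(rlspanel:::modal_value(c(8, 8, 2)), 8)
})

test_that("external validation transfers averaged parameters", {
  tab <- small_planted_table(6, n = 220)
  vcfg <- synthetic_config(
    n_samples = 300, n_progressors = 75, n_targeted = 2, n_untargeted = 20,
    planted_effects = data.frame(feature = c("glucose", "mannose"),
                                 log_or = c(log(2.5), log(2.0))),
    marker_correlations = data.frame(a = "glucose", b = "mannose", rho = 0.5),
    missing_rate = 0, seed = 61
  )
  vtab <- standardise(generate_validation_cohort(vcfg, c("glucose", "mannose")))$table
  cfg <- rls_config(lambda_grid = 2^seq(-3, 9, 3))
  # one repetition is exactly choose-lambda + single fit + predict
  plan1 <- cv_plan(3, 3, 1, seed = 5)
  ev <- external_validation(tab, vtab, c("glucose", "mannose"), cfg, plan1)
  lam <- ev$lambdas[1]
  m <- fit_rls(tab$features[, c("glucose", "mannose")], tab$outcome * 2 - 1,
               rls_config(lambda = lam))
  expect_equal(ev$scores, predict(m, vtab$features[, c("glucose", "mannose")]))
  # averaging identical models returns that model
  cfg1 <- rls_config(lambda_grid = 4)
  ev2 <- external_validation(tab, vtab, c("glucose", "mannose"), cfg1, cv_plan(3, 3, 5, seed = 5))
  m4 <- fit_rls(tab$features[, c("glucose", "mannose")], tab$outcome * 2 - 1,
                rls_config(lambda = 4))
  expect_equal(ev2$model$weights, m4$weights, tolerance = 1e-12)
  # transferred model discriminates in the validation cohort
  expect_gt(auc(ev2$scores, vtab$outcome), 0.65)
  expect_error(external_validation(tab, vtab, c("glucose", "umet_0001"), cfg, plan1),
               "umet_0001")
})
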