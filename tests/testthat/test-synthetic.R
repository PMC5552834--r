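# Synthetic-cohort generator: calibration, determinism, planted-effect
# recovery, missingness, validation cohorts.

test_that("cohort calibration is exact and generation is deterministic", {
  cfg <- synthetic_config(seed = 7)
  coh <- generate_cohort(cfg)
  expect_equal(length(coh$sample_ids), 543L)
  expect_equal(sum(coh$outcome), 146L)
  expect_equal(ncol(coh$features), 568L)
  expect_equal(sum(coh$feature_meta$panel == "targeted"), 26L)
  expect_equal(sum(coh$feature_meta$panel == "untargeted"), 542L)
  expect_identical(coh, generate_cohort(cfg)) # bit-identical for same config
  cfg2 <- synthetic_config(seed = 8)
  expect_false(identical(generate_cohort(cfg2)$features, coh$features))
  # calibration holds for arbitrary sizes/seeds
  for (s in 1:5) {
    cc <- null_cohort_config(s, n_samples = 200 + 10 * s, n_progressors = 31 + s,
                             n_targeted = 3, n_untargeted = 5)
    expect_equal(sum(generate_cohort(cc)$outcome), 31L + s)
  }
})

test_that("null cohorts carry no association signal", {
  cfg <- null_cohort_config(seed = 3, n_samples = 400, n_progressors = 108,
                            n_targeted = 5, n_untargeted = 45, missing_rate = 0)
  tab <- standardise(generate_cohort(cfg))$table
  screen <- association_screen(tab)
  expect_true(all(abs(log(screen$odds_ratio)) < 0.45))
  expect_lt(mean(screen$p_value < 0.05), 0.15) # ~5% nominal
  expect_equal(sum(screen$significant), 0L)
})

test_that("a single planted per-SD odds ratio is recovered within its Wald CI", {
  hits <- vapply(1:50, function(s) {
    tab <- standardise(generate_cohort(single_marker_config(s, log(2.18), n_samples = 5000L)))$table
    a <- feature_association(tab, "glucose")
    a$ci_low <= 2.18 && 2.18 <= a$ci_high
  }, logical(1))
  expect_gte(sum(hits), 44) # ~95% nominal coverage, 50 seeds
})

test_that("marker correlations are honoured and infeasible ones are rejected", {
  cfg <- synthetic_config(seed = 12, missing_rate = 0)
  coh <- generate_cohort(cfg)
  r <- cor(coh$features[, "glucose"], coh$features[, "mannose"])
  expect_gt(r, 0.6)
  expect_lt(r, 0.8)
  pe <- data.frame(feature = c("a", "b", "c"), log_or = c(0.1, 0.1, 0.1))
  mc <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"), rho = c(0.9, 0.9, -0.9))
  bad <- synthetic_config(planted_effects = pe, marker_correlations = mc, seed = 1)
  expect_error(generate_cohort(bad), "positive definite")
  expect_error(synthetic_config(marker_correlations = data.frame(a = "glucose", b = "nope", rho = 0.5)),
               "nope")
})

test_that("missingness injection matches its binomial law and keeps features observed", {
  cfg <- null_cohort_config(seed = 4, missing_rate = 0)
  coh <- generate_cohort(cfg)
  expect_identical(inject_missingness(coh, 0), coh)
  m <- inject_missingness(coh, 0.1, seed = 9)
  expect_identical(m, inject_missingness(coh, 0.1, seed = 9))
  frac <- mean(is.na(m$features))
  ncell <- length(m$features)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / ncell))
  idx <- !is.na(m$features)
  expect_identical(m$features[idx], coh$features[idx]) # surviving cells untouched
  # extreme rate: every feature still keeps at least one observed value
  small <- generate_cohort(null_cohort_config(5, n_samples = 40,
                                                              n_progressors = 10,
                                                              n_targeted = 2,
                                                              n_untargeted = 6,
                                                              missing_rate = 0))
  h <- inject_missingness(small, 0.9, seed = 2)
  expect_true(all(colSums(!is.na(h$features)) >= 1))
  expect_error(inject_missingness(coh, 1), "rate")
})

test_that("validation cohorts follow the same law on a restricted feature set", {
  vcfg <- synthetic_config(n_samples = 1044, n_progressors = 231, seed = 6)
  measured <- c("glucose", "mannose", "alpha_HB", "alpha_tocopherol")
  v <- generate_validation_cohort(vcfg, measured)
  expect_equal(colnames(v$features), measured)
  expect_equal(sum(v$outcome), 231L)
  expect_equal(length(v$sample_ids), 1044L)
  expect_error(generate_validation_cohort(vcfg, c("glucose", "not_a_feature")), "not_a_feature")
  # independent stream: not a copy of the training cohort draw
  tr <- generate_cohort(synthetic_config(seed = 6))
  expect_false(isTRUE(all.equal(tr$features[1:100, "glucose"], v$features[1:100, "glucose"])))
  # same law: summary moments agree within Monte-Carlo error at large n
  big <- synthetic_config(n_samples = 20000, n_progressors = 5380, n_targeted = 3,
                          n_untargeted = 7, missing_rate = 0, seed = 10)
  g1 <- generate_cohort(big)
  g2 <- generate_validation_cohort(big, colnames(g1$features))
  expect_lt(max(abs(colMeans(g1$features) - colMeans(g2$features))), 0.1)
  expect_lt(abs(cor(g1$features[, "glucose"], g1$features[, "mannose"]) -
                cor(g2$features[, "glucose"], g2$features[, "mannose"])), 0.05)
})

test_that("covariates separate the classes as configured", {
  coh <- generate_cohort(synthetic_config(seed = 20))
  cm <- bps_covariate_model()
  a <- coh$covariates$age
  expect_gt(mean(a[coh$outcome == 1]), mean(a[coh$outcome == 0]))
  fh <- coh$covariates$family_history
  expect_gt(mean(is.na(fh)), 0.25) # family history mostly recorded late
  expect_true(all(coh$covariates$sex %in% c("male", "female")))
})
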