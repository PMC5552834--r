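# Logistic association screening, q-values and baseline-characteristics tests.

test_that("logistic OR for a binary predictor equals the cross-product ratio", {
  # 2x2 counts laid out as (exposed case 99, exposed control 190,
  # unexposed case 3, unexposed control 27)
  x <- rep(c(1, 1, 0, 0), c(99, 190, 3, 27))
  y <- rep(c(1, 0, 1, 0), c(99, 190, 3, 27))
  fit <- logistic_fit(matrix(x, dimnames = list(NULL, "fh")), y)
  expect_equal(exp(unname(fit$coefficients["fh"])), (27 * 99) / (3 * 190), tolerance = 1e-6)
})

test_that("IRLS agrees with the reference implementation", {
  set.seed(42)
  X <- matrix(rnorm(400 * 3), 400, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(400, 1, plogis(0.3 + X %*% c(0.8, -0.4, 0)))
  fit <- logistic_fit(X, y)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$vcov))), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  expect_true(fit$converged)
  expect_false(fit$separation)
})

test_that("separation is flagged, not silently reported", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  fit <- logistic_fit(matrix(x, dimnames = list(NULL, "x")), y)
  expect_true(fit$separation)
  expect_error(logistic_fit(matrix(rep(1, 40), dimnames = list(NULL, "k")), y), "constant")
})

test_that("adjustment behaves as conditioning should", {
  set.seed(7)
  n <- 4000
  z <- rnorm(n)                     # confounder/mediator
  x <- z + 0.4 * rnorm(n)           # feature driven by z
  y <- rbinom(n, 1, plogis(-1 + 1.2 * z))
  tab <- cohort_table(sprintf("S%04d", 1:n),
                      cbind(feat = (x - mean(x)) / sd(x)),
                      data.frame(name = "feat", panel = "untargeted", identified = "yes"),
                      data.frame(z = z, w = rnorm(n)), y)
  un <- feature_association(tab, "feat")
  cond <- feature_association(tab, "feat", "z")
  expect_gt(un$odds_ratio, 1.5)
  expect_lt(abs(log(cond$odds_ratio)), 0.12) # collapses under conditioning
  # orthogonal adjustment leaves the OR essentially unchanged
  orth <- feature_association(tab, "feat", "w")
  expect_equal(log(orth$odds_ratio), log(un$odds_ratio), tolerance = 0.02)
})

test_that("q-values reproduce Benjamini-Hochberg with pi0 = 1 and stay monotone", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03), bh = TRUE), c(0.03, 0.03, 0.03))
  expect_equal(qvalues(0.2, bh = TRUE), 0.2)
  set.seed(1)
  p <- runif(500)^1.5
  q <- qvalues(p)
  expect_false(is.unsorted(q[order(p)])) # monotone in ranked p
  expect_true(all(q <= qvalues(p, bh = TRUE) + 1e-12)) # pi0 <= 1
  expect_true(all(q <= 1) && all(q > 0))
  expect_equal(qvalues(p, bh = TRUE), p.adjust(p, "BH"))
  expect_error(qvalues(numeric(0)), "empty")
  expect_error(qvalues(c(0.5, 0)), "0, 1")
  expect_error(qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("the screen finds planted features and controls the FDR", {
  counts <- t(vapply(1:3, function(s) {
    pe <- data.frame(feature = sprintf("pl_%02d", 1:10),
                     log_or = rep(c(log(1.7), -log(1.7)), 5))
    cfg <- synthetic_config(n_samples = 2000, n_progressors = 538, n_targeted = 10,
                            n_untargeted = 558, planted_effects = pe,
                            marker_correlations = data.frame(a = character(), b = character(),
                                                             rho = numeric()),
                            missing_rate = 0, seed = s)
    tab <- standardise(generate_cohort(cfg))$table
    sc <- association_screen(tab)
    sig <- sc$feature[sc$significant]
    c(planted = sum(sprintf("pl_%02d", 1:10) %in% sig),
      nulls = sum(!sig %in% sprintf("pl_%02d", 1:10)))
  }, numeric(2)))
  expect_gte(median(counts[, "planted"]), 8)
  expect_lte(median(counts[, "nulls"]), 1)
})

test_that("screen output is structurally sound and splits directions", {
  tab <- standardise(generate_cohort(single_marker_config(3, log(2.0), n_samples = 800)))$table
  sc <- association_screen(tab, adjustment_sets = list(character(), "age"))
  expect_equal(nrow(sc), 2L * ncol(tab$features))
  expect_true(all(sc$ci_low <= sc$odds_ratio & sc$odds_ratio <= sc$ci_high))
  expect_setequal(unique(sc$adjustment_set), c("", "age"))
  expect_equal(sc$direction[sc$feature == "glucose" & sc$adjustment_set == ""], "positive")
  tf <- tempfile(fileext = ".tsv")
  write_association(sc, tf)
  back <- read.delim(tf)
  expect_equal(nrow(back), nrow(sc))
})

test_that("baseline characteristics reproduce the printed cohort contrasts", {
  # family-history 2x2 (27 no / 190 yes in non-progressors; 3 / 99 in progressors)
  fh <- rep(c("no", "yes", "no", "yes"), c(27, 190, 3, 99))
  y <- rep(c(0, 0, 1, 1), c(27, 190, 3, 99))
  n <- length(y)
  tab <- cohort_table(sprintf("S%03d", 1:n), cbind(f1 = rnorm(n)),
                      data.frame(name = "f1", panel = "targeted", identified = "yes"),
                      data.frame(family_history = fh), y)
  bc <- baseline_characteristics(tab, "family_history")
  expect_equal(bc$test, "fisher")
  expect_equal(round(bc$p_value, 2), 0.01)
  # age comparison from printed summaries: 48.22 +/- 0.72 vs 52.34 +/- 0.99
  w <- welch_from_summary(397, 48.22, 0.72, 146, 52.34, 0.99)
  expect_lt(abs(w$p_value - 0.00089), 3e-4)
  expect_lt(w$statistic, 0)
  # identical groups: Fisher p = 1 and Welch t = 0
  y2 <- rep(c(0, 1), each = 20)
  tab2 <- cohort_table(sprintf("T%02d", 1:40), cbind(f1 = rnorm(40)),
                       data.frame(name = "f1", panel = "targeted", identified = "yes"),
                       data.frame(g = rep(c("a", "b"), 20), v = rep(c(1, 2), 20)), y2)
  bc2 <- baseline_characteristics(tab2)
  expect_equal(bc2$p_value[bc2$variable == "g"], 1)
  expect_equal(bc2$statistic[bc2$variable == "v"], 0, tolerance = 1e-12)
})
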