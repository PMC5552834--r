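# Univariate and covariate-adjusted logistic association screening, q-values,
# and baseline-characteristics tests.

# Numeric design matrix for a set of clinical covariates: numeric columns pass
# through, categorical columns become treatment-coded dummies (first level,
# alphabetically, is the reference). Rows must be complete for the requested
# covariates (use exclude_missing_covariates first).
covariate_design <- function(table, covariates) {
  if (length(covariates) == 0L) {
    return(matrix(0, length(table$sample_ids), 0))
  }
  absent <- setdiff(covariates, names(table$covariates))
  if (length(absent)) stopf("unknown covariate(s): %s", paste(absent, collapse = ", "))
  df <- table$covariates[covariates]
  if (anyNA(df)) {
    stopf("missing covariate values for %s; apply exclude_missing_covariates first",
          paste(covariates[vapply(df, anyNA, logical(1))], collapse = ", "))
  }
  cols <- lapply(covariates, function(v) {
    x <- df[[v]]
    if (is.numeric(x)) {
      m <- matrix(x, dimnames = list(NULL, v))
    } else {
      lev <- sort(unique(as.character(x)))
      if (length(lev) < 2L) {
        m <- matrix(numeric(length(x)), ncol = 1, dimnames = list(NULL, v))
        m <- m[, 0, drop = FALSE] # single level carries no information
      } else {
        m <- vapply(lev[-1], function(l) as.numeric(x == l), numeric(length(x)))
        colnames(m) <- paste0(v, "_", lev[-1])
      }
    }
    m
  })
  do.call(cbind, cols)
}

#' Maximum-likelihood logistic regression by IRLS
#'
#' Fits a binary logistic model by iteratively reweighted least squares with
#' explicit convergence and separation diagnostics. The Wald covariance is the
#' inverse observed information at the optimum.
#'
#' @param predictors numeric matrix (no intercept column; one is added).
#' @param outcome binary vector (0/1).
#' @param max_iter iteration cap (default 100).
#' @return list with `coefficients` (named, `(Intercept)` first), `vcov`,
#'   `loglik`, `iterations`, `converged`, and `separation` (TRUE when
#'   coefficients diverge as under quasi-complete separation; such fits are
#'   flagged, never silently returned as converged estimates).
#' @export
logistic_fit <- function(predictors, outcome, max_iter = 100L) {
  X <- cbind(`(Intercept)` = 1, as.matrix(predictors))
  y <- as_01(outcome)
  if (length(unique(y)) < 2L) stopf("outcome must contain both classes")
  if (ncol(X) > 1L) {
    sds <- apply(X[, -1, drop = FALSE], 2, sd1)
    if (any(sds == 0)) {
      stopf("constant predictor(s): %s", paste(colnames(X)[-1][sds == 0], collapse = ", "))
    }
  }
  beta <- numeric(ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  separation <- FALSE
  prev_max <- 0
  grow_steps <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    score <- drop(crossprod(X, y - p))
    info <- crossprod(X * w, X)
    beta <- beta + solve(info, score)
    ll <- sum(y * stats::plogis(drop(X %*% beta), log.p = TRUE) +
                (1 - y) * stats::plogis(-drop(X %*% beta), log.p = TRUE))
    cur_max <- max(abs(beta[-1]), 0)
    grow_steps <- if (cur_max >= prev_max - 1e-12) grow_steps + 1L else 0L
    prev_max <- cur_max
    if (cur_max > 15 && grow_steps >= 3L) {
      separation <- TRUE
      break
    }
    if (max(abs(score)) < 1e-8 || abs(ll - ll_old) < 1e-10 * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!converged && !separation) stopf("IRLS did not converge in %d iterations", max_iter)
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  info <- crossprod(X * pmax(p * (1 - p), 1e-12), X)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(
    coefficients = stats::setNames(beta, colnames(X)),
    vcov = vc,
    loglik = sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300))),
    iterations = it,
    converged = converged,
    separation = separation
  )
}

#' Per-SD odds ratio of one metabolite, optionally covariate-adjusted
#'
#' Logistic regression of progression on a (standardised) feature, with the
#' adjustment covariates as additional terms. The reported odds ratio is per
#' one SD of the feature; the 95% CI is Wald (`exp(coef +/- 1.96 SE)`).
#'
#' @param table a preprocessed [cohort_table()].
#' @param feature feature name.
#' @param adjustment_set character vector of covariate names (empty =
#'   unadjusted). Samples missing any of them are excluded for this analysis.
#' @return one-row data.frame: feature, odds_ratio, ci_low, ci_high, p_value,
#'   q_value (NA here; filled by [association_screen()]), adjustment_set,
#'   separation flag.
#' @export
feature_association <- function(table, feature, adjustment_set = character()) {
  if (!feature %in% colnames(table$features)) stopf("unknown feature: %s", feature)
  tab <- exclude_missing_covariates(table, adjustment_set)
  X <- cbind(
    matrix(tab$features[, feature], dimnames = list(NULL, feature)),
    covariate_design(tab, adjustment_set)
  )
  fit <- logistic_fit(X, tab$outcome)
  b <- fit$coefficients[feature]
  se <- sqrt(fit$vcov[feature, feature])
  z <- b / se
  data.frame(
    feature = feature,
    odds_ratio = exp(b),
    ci_low = exp(b - stats::qnorm(0.975) * se),
    ci_high = exp(b + stats::qnorm(0.975) * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    q_value = NA_real_,
    adjustment_set = paste(adjustment_set, collapse = "+"),
    separation = fit$separation,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Storey q-values for false-discovery-rate control
#'
#' Plug-in estimate `pi0 = #\{p > lambda\} / (m (1 - lambda))` at a fixed
#' `lambda = 0.5` (clipped to (0, 1]), then
#' `q_i = min_\{p_(j) >= p_(i)\} pi0 m p_(j) / j`. With `pi0 = 1` (argument
#' `bh = TRUE`) this is exactly the Benjamini-Hochberg adjusted p-value.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param lambda tuning point for the pi0 plug-in (default 0.5).
#' @param bh logical; force `pi0 = 1` (plain Benjamini-Hochberg).
#' @return vector of q-values, same order as the input.
#' @export
qvalues <- function(p_values, lambda = 0.5, bh = FALSE) {
  m <- length(p_values)
  if (m == 0L) stopf("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  pi0 <- if (bh) 1 else min(1, max(sum(p_values > lambda) / (m * (1 - lambda)), 1 / m))
  ord <- order(p_values)
  q <- pi0 * m * p_values[ord] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Metabolome-wide association screen
#'
#' Runs [feature_association()] for every feature under each adjustment set,
#' attaches q-values per screen, and labels significance at q < 0.05 split
#' into positive (OR > 1) and negative (OR < 1) associations. Per-feature fit
#' failures are recorded (`error` column) and the screen continues.
#'
#' @param table a preprocessed [cohort_table()].
#' @param adjustment_sets list of covariate-name vectors; default one
#'   unadjusted screen.
#' @param bh passed to [qvalues()].
#' @return data.frame of class `association_screen`, one row per feature per
#'   adjustment set.
#' @export
association_screen <- function(table, adjustment_sets = list(character()), bh = FALSE) {
  screens <- lapply(adjustment_sets, function(adj) {
    rows <- lapply(colnames(table$features), function(f) {
      tryCatch(
        cbind(feature_association(table, f, adj), error = NA_character_,
              stringsAsFactors = FALSE),
        error = function(e) {
          data.frame(
            feature = f, odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
            p_value = NA_real_, q_value = NA_real_,
            adjustment_set = paste(adj, collapse = "+"),
            separation = NA, error = conditionMessage(e), stringsAsFactors = FALSE
          )
        }
      )
    })
    out <- do.call(rbind, rows)
    ok <- !is.na(out$p_value)
    if (any(ok)) out$q_value[ok] <- qvalues(out$p_value[ok], bh = bh)
    out$significant <- !is.na(out$q_value) & out$q_value < 0.05
    out$direction <- ifelse(is.na(out$odds_ratio), NA_character_,
                            ifelse(out$odds_ratio > 1, "positive", "negative"))
    out
  })
  out <- do.call(rbind, screens)
  rownames(out) <- NULL
  class(out) <- c("association_screen", class(out))
  out
}

#' Welch's two-sample t test from summary statistics
#'
#' Accepts group size, mean and standard error of the mean, as printed in a
#' baseline-characteristics table, and applies the Welch-Satterthwaite
#' approximation.
#'
#' @param n1,mean1,sem1 first group; @param n2,mean2,sem2 second group.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
welch_from_summary <- function(n1, mean1, sem1, n2, mean2, sem2) {
  v1 <- sem1^2
  v2 <- sem2^2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Baseline characteristics comparison between progressors and non-progressors
#'
#' Categorical covariates are compared by Fisher's exact test (exact for 2xC;
#' larger tables fall back to a seeded Monte-Carlo p with 1e5 draws) and
#' continuous covariates by Welch's two-sample t test. Variables with a single
#' observed level are skipped with a note. Missing values are excluded
#' per-variable.
#'
#' @param table a [cohort_table()].
#' @param variables covariate names (default all).
#' @param seed seed for Monte-Carlo Fisher p-values.
#' @return data.frame: variable, test, statistic, p_value, note.
#' @export
baseline_characteristics <- function(table, variables = names(table$covariates), seed = 1L) {
  y <- factor(table$outcome, levels = c(0, 1), labels = c("nonprogressor", "progressor"))
  rows <- lapply(variables, function(v) {
    x <- table$covariates[[v]]
    if (is.null(x)) stopf("unknown covariate: %s", v)
    ok <- !is.na(x)
    x <- x[ok]
    yy <- y[ok]
    if (is.numeric(x)) {
      if (length(unique(x)) < 2L || min(table(yy)) < 2L) {
        return(data.frame(variable = v, test = "welch", statistic = NA_real_,
                          p_value = NA_real_, note = "insufficient data",
                          stringsAsFactors = FALSE))
      }
      tt <- stats::t.test(x ~ yy)
      data.frame(variable = v, test = "welch", statistic = unname(tt$statistic),
                 p_value = tt$p.value, note = NA_character_, stringsAsFactors = FALSE)
    } else {
      tab <- table(x, yy)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (nrow(tab) < 2L) {
        return(data.frame(variable = v, test = "fisher", statistic = NA_real_,
                          p_value = NA_real_, note = "single observed level",
                          stringsAsFactors = FALSE))
      }
      p <- if (nrow(tab) <= 2L) {
        stats::fisher.test(tab)$p.value
      } else {
        with_seed(seed, stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e5)$p.value)
      }
      data.frame(variable = v, test = "fisher", statistic = NA_real_,
                 p_value = p, note = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an association screen as TSV
#'
#' @param screen result of [association_screen()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_association <- function(screen, path) {
  utils::write.table(screen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
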