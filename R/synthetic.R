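#' Class-conditional clinical covariate model of the training cohort
#'
#' Default generative model for the clinical covariates, with class-conditional
#' means and standard deviations (SD back-computed from the published SEMs as
#' SEM * sqrt(n), with n = 397 non-progressors and 146 progressors) and
#' class-conditional category/missingness probabilities for the categorical
#' variables. Continuous covariates are drawn as Gaussians; this reproduces the
#' group separations of the source cohort qualitatively, not its joint
#' covariate distribution.
#'
#' @return A named list, one entry per covariate, each a list with `type`
#'   (`"continuous"`/`"categorical"`) and class-conditional parameters. Class
#'   names are `nonprogressor` and `progressor`.
#' @export
bps_covariate_model <- function() {
  cont <- function(m0, s0, m1, s1, miss0 = 0, miss1 = 0) {
    list(
      type = "continuous",
      mean = c(nonprogressor = m0, progressor = m1),
      sd = c(nonprogressor = s0, progressor = s1),
      missing = c(nonprogressor = miss0, progressor = miss1)
    )
  }
  cat_ <- function(levels, p0, p1, miss0 = 0, miss1 = 0) {
    list(
      type = "categorical", levels = levels,
      prob = rbind(nonprogressor = p0 / sum(p0), progressor = p1 / sum(p1)),
      missing = c(nonprogressor = miss0, progressor = miss1)
    )
  }
  s <- function(sem, n) sem * sqrt(n)
  list(
    sex = cat_(c("male", "female"), c(200, 197), c(74, 72)),
    age = cont(48.22, s(0.72, 397), 52.34, s(0.99, 146)),
    bmi = cont(25.91, s(0.19, 397), 28.46, s(0.37, 146)),
    waist = cont(88.19, s(0.59, 397), 96.15, s(1.04, 146)),
    fasting_glucose = cont(5.60, s(0.03, 397), 5.90, s(0.05, 146)),
    fasting_insulin = cont(38.85, s(1.26, 397), 59.34, s(4.71, 146)),
    sbp = cont(129.47, s(0.95, 397), 138.87, s(1.60, 146)),
    dbp = cont(78.70, s(0.55, 397), 83.94, s(0.86, 146)),
    total_cholesterol = cont(5.68, s(0.07, 397), 5.81, s(0.09, 146)),
    hdl_cholesterol = cont(1.35, s(0.01, 397), 1.27, s(0.03, 146)),
    triacylglycerols = cont(1.34, s(0.04, 397), 1.69, s(0.08, 146)),
    family_history = cat_(c("no", "yes"), c(27, 190), c(3, 99),
      miss0 = 180 / 397, miss1 = 44 / 146
    ),
    future_cvd = cat_(c("no", "yes"), c(305, 92), c(114, 32)),
    physical_activity = cat_(c("low", "medium", "high"), c(12, 222, 146), c(6, 93, 38),
      miss0 = 17 / 397, miss1 = 9 / 146
    ),
    hypertension_medication = cat_(c("no", "yes"), c(214, 41), c(61, 19),
      miss0 = 142 / 397, miss1 = 66 / 146
    )
  )
}

#' Default planted marker effects
#'
#' Per-SD odds ratios for the seven-marker panel used as the default planted
#' signal: two strongly predictive sugars (a glucose-like and a mannose-like
#' feature, correlated), two unidentified features, alpha-hydroxybutyrate,
#' alpha-tocopherol and a bradykinin-hydroxyproline-like peptide.
#'
#' @return data.frame with columns `feature` and `log_or`.
#' @export
default_planted_effects <- function() {
  data.frame(
    feature = c(
      "glucose", "mannose", "X12063", "alpha_HB",
      "X13435", "alpha_tocopherol", "Hyp3_BK"
    ),
    log_or = log(c(2.18, 2.05, 1.86, 1.57, 0.82, 0.62, 0.55)),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the emulated training cohort: 543 samples of whom 146
#' progress to type 2 diabetes, 26 targeted (quantitative) plus 542 untargeted
#' (semi-quantitative) metabolite features, seven planted markers at the
#' per-SD odds ratios of the published panel, a 0.7 correlation between the
#' glucose-like and mannose-like features, equicorrelated blocks of null
#' features, and 5% missing-at-random cells.
#'
#' @param n_samples,n_progressors cohort size and number of progressors
#'   (`n_progressors < n_samples`).
#' @param n_targeted,n_untargeted feature counts per panel.
#' @param planted_effects data.frame (`feature`, `log_or`) of per-SD log odds
#'   ratios driving the outcome; empty frame gives a null cohort.
#' @param marker_correlations data.frame (`a`, `b`, `rho`) of pairwise Pearson
#'   correlations between planted features, |rho| < 1.
#' @param covariate_model class-conditional covariate model, see
#'   [bps_covariate_model()].
#' @param block_correlation length-2 numeric `c(size, rho)`: null features are
#'   drawn in equicorrelated blocks of `size` features with within-block
#'   correlation `rho`.
#' @param missing_rate fraction in [0, 1) of feature cells set missing
#'   (missing completely at random).
#' @param seed integer; generation is a pure function of the configuration,
#'   including this seed.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 543L,
                             n_progressors = 146L,
                             n_targeted = 26L,
                             n_untargeted = 542L,
                             planted_effects = default_planted_effects(),
                             marker_correlations = data.frame(
                               a = "glucose", b = "mannose", rho = 0.7,
                               stringsAsFactors = FALSE
                             ),
                             covariate_model = bps_covariate_model(),
                             block_correlation = c(size = 8, rho = 0.3),
                             missing_rate = 0.05,
                             seed = 1L) {
  cfg <- structure(
    list(
      n_samples = as.integer(n_samples),
      n_progressors = as.integer(n_progressors),
      n_targeted = as.integer(n_targeted),
      n_untargeted = as.integer(n_untargeted),
      planted_effects = planted_effects,
      marker_correlations = marker_correlations,
      covariate_model = covariate_model,
      block_correlation = unname(block_correlation),
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_progressors <= 0L || cfg$n_progressors >= cfg$n_samples) {
    stopf("n_progressors must be in (0, n_samples); got %d of %d", cfg$n_progressors, cfg$n_samples)
  }
  if (cfg$n_targeted + cfg$n_untargeted < 1L) stopf("need at least one feature")
  pe <- cfg$planted_effects
  if (nrow(pe) && anyDuplicated(pe$feature)) stopf("planted feature names must be unique")
  mc <- cfg$marker_correlations
  if (nrow(mc)) {
    if (any(abs(mc$rho) >= 1)) stopf("all |rho| must be < 1")
    unknown <- setdiff(c(mc$a, mc$b), pe$feature)
    if (length(unknown)) {
      stopf("marker_correlations may only reference planted features; unknown: %s",
            paste(unknown, collapse = ", "))
    }
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) stopf("missing_rate must be in [0, 1)")
  if (length(cfg$block_correlation) != 2L || cfg$block_correlation[1] < 1 ||
      abs(cfg$block_correlation[2]) >= 1) {
    stopf("block_correlation must be c(size >= 1, |rho| < 1)")
  }
  invisible(cfg)
}

# Feature name layout: planted names are substituted into the appropriate
# panel (alpha_HB is targeted/quantitative, the rest untargeted, mirroring the
# panel membership the defaults emulate); remaining slots are filler nulls.
synthetic_feature_names <- function(cfg) {
  planted <- cfg$planted_effects$feature
  targeted_planted <- intersect(planted, c("alpha_HB", "glutamate"))
  untargeted_planted <- setdiff(planted, targeted_planted)
  if (length(targeted_planted) > cfg$n_targeted) {
    # fall back: overflow planted features go to the untargeted panel
    untargeted_planted <- c(untargeted_planted, targeted_planted[-seq_len(cfg$n_targeted)])
    targeted_planted <- targeted_planted[seq_len(cfg$n_targeted)]
  }
  if (length(untargeted_planted) > cfg$n_untargeted) {
    stopf("more planted features (%d) than feature slots", length(planted))
  }
  filler <- function(prefix, n, avoid) {
    pool <- setdiff(sprintf("%s_%04d", prefix, seq_len(n + length(avoid))), avoid)
    pool[seq_len(n)]
  }
  targeted <- c(targeted_planted,
                filler("tmet", cfg$n_targeted - length(targeted_planted), planted))
  untargeted <- c(untargeted_planted,
                  filler("umet", cfg$n_untargeted - length(untargeted_planted), planted))
  meta <- data.frame(
    name = c(targeted, untargeted),
    panel = rep(c("targeted", "untargeted"), c(length(targeted), length(untargeted))),
    identified = "yes",
    stringsAsFactors = FALSE
  )
  meta$identified[grepl("^X[0-9]", meta$name)] <- "no"
  meta
}

# Draw the latent standardised feature matrix: planted features jointly
# Gaussian with the configured pairwise correlations, null features in
# equicorrelated blocks (single-factor construction).
draw_latent_features <- function(cfg, n, meta) {
  p <- nrow(meta)
  Z <- matrix(0, n, p, dimnames = list(NULL, meta$name))
  planted <- cfg$planted_effects$feature
  if (length(planted)) {
    R <- diag(length(planted))
    dimnames(R) <- list(planted, planted)
    mc <- cfg$marker_correlations
    if (nrow(mc)) {
      for (i in seq_len(nrow(mc))) {
        R[mc$a[i], mc$b[i]] <- R[mc$b[i], mc$a[i]] <- mc$rho[i]
      }
    }
    ch <- tryCatch(chol(R), error = function(e) {
      stopf("correlation matrix of planted features (%s) is not positive definite",
            paste(planted, collapse = ", "))
    })
    Z[, planted] <- matrix(rnorm(n * length(planted)), n) %*% ch
  }
  nulls <- setdiff(meta$name, planted)
  if (length(nulls)) {
    bs <- max(1L, as.integer(cfg$block_correlation[1]))
    rho <- cfg$block_correlation[2]
    if (rho < 0) stopf("negative within-block correlations are not supported")
    block <- rep(seq_len(ceiling(length(nulls) / bs)), each = bs)[seq_along(nulls)]
    g <- matrix(rnorm(n * max(block)), n)
    e <- matrix(rnorm(n * length(nulls)), n)
    Z[, nulls] <- sqrt(rho) * g[, block] + sqrt(1 - rho) * e
  }
  Z
}

# Class-conditional covariate draw for n samples with outcome y (0/1).
draw_covariates <- function(model, y) {
  n <- length(y)
  cls <- ifelse(y == 1, "progressor", "nonprogressor")
  out <- lapply(names(model), function(nm) {
    m <- model[[nm]]
    if (m$type == "continuous") {
      v <- rnorm(n, mean = m$mean[cls], sd = m$sd[cls])
    } else {
      v <- character(n)
      for (cl in c("nonprogressor", "progressor")) {
        idx <- which(cls == cl)
        if (length(idx)) {
          v[idx] <- sample(m$levels, length(idx), replace = TRUE, prob = m$prob[cl, ])
        }
      }
    }
    miss <- m$missing %||% c(nonprogressor = 0, progressor = 0)
    pm <- unname(miss[cls])
    if (any(pm > 0)) v[runif(n) < pm] <- NA
    v
  })
  names(out) <- names(model)
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Calibrated outcome assignment: the linear predictor is sum(beta_j * Z_j); a
# sample becomes a progressor when intercept + LP_i > logit(U_i). The realised
# count is a non-decreasing step function of the intercept, so the bisection
# the calibration prescribes converges to the k-th order statistic of
# t_i = logit(U_i) - LP_i; we take that exact limit.
assign_outcome <- function(lp, k) {
  n <- length(lp)
  t <- stats::qlogis(stats::runif(n)) - lp
  ord <- order(t)
  y <- integer(n)
  y[ord[seq_len(k)]] <- 1L
  intercept <- mean(sort(t)[c(k, min(k + 1L, n))])
  list(outcome = y, intercept = intercept)
}

generate_cohort_impl <- function(cfg, seed) {
  meta <- synthetic_feature_names(cfg)
  with_seed(seed, {
    n <- cfg$n_samples
    Z <- draw_latent_features(cfg, n, meta)
    pe <- cfg$planted_effects
    lp <- if (nrow(pe)) drop(Z[, pe$feature, drop = FALSE] %*% pe$log_or) else rep(0, n)
    oc <- assign_outcome(lp, cfg$n_progressors)
    # observed scale: per-feature location/scale so preprocessing has work to
    # do; drawn from a stream fixed by the feature layout (not the cohort
    # seed) so training and validation cohorts share one measurement scale
    ms <- with_seed(mix_seed(777L, ncol(Z)), list(mu = runif(ncol(Z), 5, 15),
                                                  sig = runif(ncol(Z), 0.5, 2)))
    mu <- ms$mu
    sig <- ms$sig
    X <- sweep(sweep(Z, 2, sig, "*"), 2, mu, "+")
    covs <- draw_covariates(cfg$covariate_model, oc$outcome)
    tab <- cohort_table(
      sample_ids = sprintf("S%04d", seq_len(n)),
      features = X,
      feature_meta = meta,
      covariates = covs,
      outcome = oc$outcome
    )
    attr(tab, "calibrated_intercept") <- oc$intercept
    if (cfg$missing_rate > 0) {
      tab <- inject_missingness(tab, cfg$missing_rate, seed = mix_seed(seed, 7L))
    }
    tab
  })
}

#' Generate a synthetic prospective cohort
#'
#' Latent metabolite features are standardised Gaussians (planted markers
#' jointly with their configured correlations, null features in equicorrelated
#' blocks); the binary progression outcome follows a logistic model on the
#' planted per-SD log odds ratios, with the intercept calibrated so the
#' realised progressor count equals `n_progressors` exactly; clinical
#' covariates are drawn class-conditionally; finally missing-at-random cells
#' are injected. Bit-identical for identical configuration + seed.
#'
#' @param config a [synthetic_config()].
#' @return A [cohort_table()] with the calibrated logistic intercept attached
#'   as attribute `"calibrated_intercept"`.
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  generate_cohort_impl(config, config$seed)
}

#' Inject missing-at-random cells into a cohort's feature matrix
#'
#' Each feature cell is independently set missing with probability `rate`;
#' features that would lose all observed values have their mask resampled so
#' every feature retains at least one observation.
#'
#' @param table a [cohort_table()].
#' @param rate missingness probability in [0, 1).
#' @param seed integer seed for the missingness mask.
#' @return The cohort with `NA`s added to its feature matrix.
#' @export
inject_missingness <- function(table, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stopf("rate must be in [0, 1)")
  if (rate == 0) return(table)
  X <- table$features
  n <- nrow(X)
  with_seed(seed, {
    for (j in seq_len(ncol(X))) {
      for (try in seq_len(1000L)) {
        mask <- stats::runif(n) < rate
        if (!all(mask | is.na(X[, j]))) break
        if (try == 1000L) {
          stopf("could not retain an observed value for feature %s at rate %.3f",
                colnames(X)[j], rate)
        }
      }
      X[mask, j] <- NA_real_
    }
  })
  table$features <- X
  table
}

#' Generate an external validation cohort
#'
#' Draws from the same generative law as [generate_cohort()] (all planted
#' features still drive the outcome) but returns only the `measured_features`
#' columns, emulating a replication cohort whose platform measured a subset of
#' the markers. An independent seed stream is derived from `config$seed`, so a
#' validation cohort never reuses the training cohort's random numbers.
#'
#' @param config a [synthetic_config()] describing the validation cohort
#'   (size, prevalence, covariate model may differ from training).
#' @param measured_features character vector of feature names to retain.
#' @return A [cohort_table()] restricted to `measured_features`.
#' @export
generate_validation_cohort <- function(config, measured_features) {
  validate_synthetic_config(config)
  meta <- synthetic_feature_names(config)
  unknown <- setdiff(measured_features, meta$name)
  if (length(unknown)) stopf("unknown feature name(s): %s", paste(unknown, collapse = ", "))
  tab <- generate_cohort_impl(config, mix_seed(config$seed, 90017L))
  subset_cohort(tab, feature_names = measured_features)
}
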