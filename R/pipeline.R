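# Orchestration: configuration, model-family resolution, the end-to-end
# analysis (generate/read -> preprocess -> associate -> model comparison ->
# panel selection -> external validation -> report) and a small CLI.

#' Default clinical reference covariates
#'
#' The reference risk-factor set (sex, age, BMI, fasting insulin, family
#' history); `extended` adds fasting glucose, `extended2` additionally adds
#' lipids, blood pressure and waist circumference.
#'
#' @param which one of "reference", "extended", "extended2".
#' @return character vector of covariate names.
#' @export
clinical_covariates <- function(which = c("reference", "extended", "extended2")) {
  which <- match.arg(which)
  base <- c("sex", "age", "bmi", "fasting_insulin", "family_history")
  switch(which,
    reference = base,
    extended = c(base, "fasting_glucose"),
    extended2 = c(base, "fasting_glucose", "total_cholesterol", "hdl_cholesterol",
                  "triacylglycerols", "sbp", "dbp", "waist")
  )
}

#' Resolve a model specification against a cohort
#'
#' Translates a model-family name into concrete feature and covariate lists:
#' `clinical-only`, `metabolome-only`, `combined`, `panel-only`,
#' `panel+clinical`, or `custom` (explicit lists).
#'
#' @param name model family.
#' @param table the analysis [cohort_table()].
#' @param panel character vector of panel features (required for the panel
#'   families).
#' @param covariates clinical covariate set for the families that use one.
#' @param feature_names,covariate_names explicit lists for `custom`.
#' @return object of class `model_spec` with resolved `feature_names` and
#'   `covariate_names`.
#' @export
model_spec <- function(name, table, panel = NULL,
                       covariates = clinical_covariates(),
                       feature_names = character(), covariate_names = character()) {
  all_feats <- colnames(table$features)
  spec <- switch(name,
    "clinical-only" = list(features = character(), covs = covariates),
    "metabolome-only" = list(features = all_feats, covs = character()),
    "combined" = list(features = all_feats, covs = covariates),
    "panel-only" = list(features = panel %||% stopf("panel required for %s", name),
                        covs = character()),
    "panel+clinical" = list(features = panel %||% stopf("panel required for %s", name),
                            covs = covariates),
    "custom" = list(features = feature_names, covs = covariate_names),
    stopf("unknown model family: %s", name)
  )
  unknown <- setdiff(spec$features, all_feats)
  if (length(unknown)) stopf("model %s: unknown feature(s) %s", name, paste(unknown, collapse = ", "))
  unknown <- setdiff(spec$covs, names(table$covariates))
  if (length(unknown)) stopf("model %s: unknown covariate(s) %s", name, paste(unknown, collapse = ", "))
  if (!length(spec$features) && !length(spec$covs)) stopf("model %s resolves to nothing", name)
  structure(list(name = name, feature_names = spec$features, covariate_names = spec$covs),
            class = "model_spec")
}

default_pipeline_config <- function() {
  list(
    outdir = "rlspanel_out",
    seed = 1L,
    cohort = list(source = "synthetic", synthetic = list()),
    association = list(enabled = TRUE, adjustment_sets = list(character())),
    cv = list(outer_folds = 10L, inner_folds = 10L, repetitions = 100L),
    rls = list(lambda_grid = 2^(-15:15), intercept = TRUE),
    selection = list(k = 5L),
    models = c("clinical-only", "metabolome-only", "combined", "panel+clinical"),
    clinical_covariates = clinical_covariates(),
    validation = list(enabled = FALSE)
  )
}

validate_pipeline_config <- function(cfg) {
  known <- names(default_pipeline_config())
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stopf("unknown config section(s): %s", paste(extra, collapse = ", "))
  if (!cfg$cohort$source %in% c("synthetic", "files")) {
    stopf("cohort$source must be 'synthetic' or 'files'")
  }
  if (cfg$cohort$source == "files" &&
      (is.null(cfg$cohort$features) || is.null(cfg$cohort$covariates))) {
    stopf("cohort$source = 'files' requires cohort$features and cohort$covariates paths")
  }
  if (cfg$cv$outer_folds < 2 || cfg$cv$inner_folds < 2 || cfg$cv$repetitions < 1) {
    stopf("cv settings invalid: folds >= 2, repetitions >= 1")
  }
  bad <- setdiff(cfg$models, c("clinical-only", "metabolome-only", "combined",
                               "panel-only", "panel+clinical"))
  if (length(bad)) stopf("unknown model famil(ies): %s", paste(bad, collapse = ", "))
  invisible(cfg)
}

read_pipeline_config <- function(config) {
  cfg <- default_pipeline_config()
  user <- if (is.character(config)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    config %||% list()
  }
  for (nm in names(user)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      utils::modifyList(cfg[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  validate_pipeline_config(cfg)
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order: cohort generation or loading,
#' preprocessing (minimum imputation, standardisation, covariate exclusion per
#' model), metabolome-wide association screening, repeated nested stratified
#' cross-validation for every configured model family, GreedyRLS panel
#' selection and union, optional external validation, and a human-readable
#' summary report (AUC mean with percentile CI, pairwise DeLong tests,
#' discrimination slopes and IDI against the clinical-only reference). All
#' outputs are plain text (TSV/JSON) under `outdir`; reruns with the same
#' configuration are numerically identical.
#'
#' @param config path to a JSON configuration file, or an equivalent named
#'   list. Unknown sections are rejected before any computation.
#' @param stages subset of stages to run (default all).
#' @return invisibly, a list with the cohort, screen, per-model results,
#'   panel, validation results and the path of the report.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "associate", "crossval", "select",
                                    "validate", "report")) {
  cfg <- read_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("rlspanel pipeline, seed %d, started %s", cfg$seed,
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(code, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    log_lines <<- c(log_lines, sprintf("stage %-10s %.1fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  # --- cohort -----------------------------------------------------------
  cohort <- stage("simulate", {
    if (cfg$cohort$source == "synthetic") {
      syn <- do.call(synthetic_config, c(cfg$cohort$synthetic, list(seed = cfg$seed)))
      tab <- generate_cohort(syn)
      write_cohort(tab, file.path(cfg$outdir, "features.tsv"),
                   file.path(cfg$outdir, "covariates.tsv"), config = syn)
      tab
    } else {
      read_cohort(cfg$cohort$features, cfg$cohort$covariates)
    }
  })

  prep <- stage("preprocess", standardise(impute_minimum(cohort)))
  table <- prep$table
  write_standardisation(prep$params, file.path(cfg$outdir, "standardisation.json"))

  screen <- NULL
  if ("associate" %in% stages && isTRUE(cfg$association$enabled)) {
    screen <- stage("associate", {
      sets <- lapply(cfg$association$adjustment_sets, as.character)
      s <- association_screen(table, sets)
      write_association(s, file.path(cfg$outdir, "association.tsv"))
      s
    })
  }

  rls_cfg <- rls_config(lambda_grid = sort(as.numeric(cfg$rls$lambda_grid)),
                        intercept = isTRUE(cfg$rls$intercept))
  plan <- cv_plan(cfg$cv$outer_folds, cfg$cv$inner_folds, cfg$cv$repetitions, cfg$seed)

  panel <- NULL
  selection_result <- NULL
  if ("select" %in% stages && any(grepl("panel", cfg$models))) {
    selection_result <- stage("select", {
      nested_cv(table, colnames(table$features), rls_cfg, plan,
                select_k = cfg$selection$k, model_spec = "greedy-selection")
    })
    panel <- panel_union(selection_result)
    jsonlite::write_json(panel$union, file.path(cfg$outdir, "panel.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  results <- list()
  if ("crossval" %in% stages) {
    for (m in cfg$models) {
      results[[m]] <- stage(paste0("crossval:", m), {
        spec <- model_spec(m, table, panel = panel$union$feature,
                           covariates = cfg$clinical_covariates)
        tab_m <- exclude_missing_covariates(table, spec$covariate_names)
        res <- nested_cv(tab_m, spec$feature_names, rls_cfg, plan,
                         covariate_set = spec$covariate_names, model_spec = m)
        write_cv_scores(res, file.path(cfg$outdir, paste0("cv_scores_", gsub("[^a-z]", "_", m), ".tsv")))
        res
      })
    }
  }

  validation <- NULL
  if ("validate" %in% stages && isTRUE(cfg$validation$enabled)) {
    validation <- stage("validate", {
      vcfg <- do.call(synthetic_config,
                      c(cfg$validation$synthetic, list(seed = mix_seed(cfg$seed, 2L))))
      measured <- as.character(cfg$validation$measured_features)
      vtab <- generate_validation_cohort(vcfg, measured)
      vprep <- standardise(impute_minimum(vtab))
      vtab_s <- vprep$table
      lapply(c("clinical-only", "combined"), function(m) {
        covs <- cfg$clinical_covariates
        feats <- if (m == "combined") measured else character()
        tr <- exclude_missing_covariates(table, covs)
        va <- exclude_missing_covariates(vtab_s, covs)
        external_validation(tr, va, feats, rls_cfg, plan, covariate_set = covs)
      }) -> runs
      names(runs) <- c("clinical-only", "combined")
      runs
    })
  }

  report_path <- NULL
  if ("report" %in% stages && length(results)) {
    report_path <- stage("report", {
      p <- file.path(cfg$outdir, "report.txt")
      writeLines(render_report(results, validation, cfg), p)
      p
    })
  }
  writeLines(c(log_lines, sprintf("finished %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(cfg$outdir, "pipeline.log"))
  invisible(list(cohort = cohort, table = table, screen = screen, results = results,
                 panel = panel, selection = selection_result, validation = validation,
                 report = report_path, config = cfg))
}

# Plain-text model comparison: AUC mean with percentile CI per model, DeLong p
# and IDI against the clinical-only reference on repetition-averaged
# out-of-fold scores restricted to commonly scored samples.
render_report <- function(results, validation, cfg) {
  lines <- c("Model comparison (repeated nested stratified cross-validation)",
             sprintf("repetitions = %d, outer = %d, inner = %d, seed = %d",
                     cfg$cv$repetitions, cfg$cv$outer_folds, cfg$cv$inner_folds, cfg$seed), "")
  avg <- lapply(results, function(r) rowMeans(r$scores))
  for (m in names(results)) {
    r <- results[[m]]
    ci <- if (length(r$auc) > 1) mean_auc_ci(r$auc) else c(mean = r$auc, ci_low = NA, ci_high = NA)
    lines <- c(lines, sprintf("%-16s AUC %.2f (95%% CI %.2f, %.2f)", m,
                              ci["mean"], ci["ci_low"], ci["ci_high"]))
  }
  ref <- "clinical-only"
  if (ref %in% names(results) && length(results) > 1) {
    lines <- c(lines, "", sprintf("Pairwise comparison against %s (repetition-averaged scores):", ref))
    for (m in setdiff(names(results), ref)) {
      common <- intersect(names(avg[[ref]]), names(avg[[m]]))
      y <- results[[m]]$outcome[match(common, rownames(results[[m]]$scores))]
      dl <- delong_test(avg[[m]][common], avg[[ref]][common], y)
      pr_new <- risk_probabilities(avg[[m]][common], sd1(avg[[m]][common]))
      pr_old <- risk_probabilities(avg[[ref]][common], sd1(avg[[ref]][common]))
      ds_new <- discrimination_slope(pr_new, y)
      ds_old <- discrimination_slope(pr_old, y)
      lines <- c(lines, sprintf(
        "%-16s vs %s: DeLong p = %.3g; DS %.2f vs %.2f; IDI = %.1f%%",
        m, ref, dl$p_value, ds_new, ds_old, idi(ds_new, ds_old)))
    }
  }
  if (!is.null(validation)) {
    lines <- c(lines, "", "External validation (averaged-model transfer):")
    for (m in names(validation)) {
      v <- validation[[m]]
      ci <- delong_ci(v$scores, v$outcome)
      lines <- c(lines, sprintf("%-16s validation AUC %.2f (95%% CI %.2f, %.2f)",
                                m, ci["auc"], ci["ci_low"], ci["ci_high"]))
    }
  }
  lines
}

#' Benchmark named marker sets
#'
#' Runs the nested cross-validation for each named feature set combined with
#' the clinical covariates and reports the AUC summaries side by side
#' (machinery for comparing any published marker sets; no scientific claim).
#' Sets containing unknown features are skipped with a warning.
#'
#' @param table preprocessed [cohort_table()].
#' @param named_sets named list of feature-name vectors.
#' @param config an [rls_config()].
#' @param plan a [cv_plan()].
#' @param covariate_set clinical covariates added to every set.
#' @return data.frame: set, n_features, mean_auc, ci_low, ci_high.
#' @export
benchmark_marker_sets <- function(table, named_sets, config = rls_config(),
                                  plan = cv_plan(), covariate_set = clinical_covariates()) {
  rows <- lapply(names(named_sets), function(nm) {
    feats <- named_sets[[nm]]
    unknown <- setdiff(feats, colnames(table$features))
    if (length(unknown)) {
      warning(sprintf("skipping set '%s': unknown feature(s) %s", nm,
                      paste(unknown, collapse = ", ")), call. = FALSE)
      return(NULL)
    }
    tab_m <- exclude_missing_covariates(table, covariate_set)
    res <- nested_cv(tab_m, feats, config, plan, covariate_set = covariate_set,
                     model_spec = nm)
    ci <- if (length(res$auc) > 1) mean_auc_ci(res$auc) else c(mean = res$auc, ci_low = NA, ci_high = NA)
    data.frame(set = nm, n_features = length(feats), mean_auc = ci["mean"],
               ci_low = ci["ci_low"], ci_high = ci["ci_high"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(set = character(), n_features = integer(), mean_auc = numeric(),
                      ci_low = numeric(), ci_high = numeric())
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `associate`, `crossval`, `select`, `validate`,
#' `report`, `all`. Flags: `--config <json>`, `--outdir`, `--seed`,
#' `--repetitions`, `--outer-folds`, `--inner-folds`, `--panel-size`. CLI
#' flags override config-file values.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the [run_pipeline()] result.
#' @export
rlspanel_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("simulate", "associate", "crossval", "select", "validate", "report", "all")
  if (length(args) == 0L || !args[1] %in% subcommands) {
    stopf("usage: rlspanel <%s> [--config file.json] [--seed N] ...",
          paste(subcommands, collapse = "|"))
  }
  sub <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--outdir", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--repetitions", type = "integer", default = NULL),
    optparse::make_option("--outer-folds", type = "integer", default = NULL),
    optparse::make_option("--inner-folds", type = "integer", default = NULL),
    optparse::make_option("--panel-size", type = "integer", default = NULL)
  ))
  opt <- optparse::parse_args(parser, args = args[-1])
  cfg <- read_pipeline_config(opt$config)
  if (!is.null(opt$outdir)) cfg$outdir <- opt$outdir
  if (!is.null(opt$seed)) cfg$seed <- opt$seed
  if (!is.null(opt$repetitions)) cfg$cv$repetitions <- opt$repetitions
  if (!is.null(opt$`outer-folds`)) cfg$cv$outer_folds <- opt$`outer-folds`
  if (!is.null(opt$`inner-folds`)) cfg$cv$inner_folds <- opt$`inner-folds`
  if (!is.null(opt$`panel-size`)) cfg$selection$k <- opt$`panel-size`
  stages <- if (sub == "all") {
    c("simulate", "associate", "crossval", "select", "validate", "report")
  } else {
    unique(c("simulate", sub, if (sub == "crossval") c("select", "report")))
  }
  invisible(run_pipeline(cfg, stages = stages))
}
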