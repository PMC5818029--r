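# End-to-end analysis pipeline and report rendering.

#' Pipeline configuration
#'
#' @param input `"fixture"`, a CSV path, or a [simulation_config()].
#' @param predictors model predictor columns (default the three-variable
#'   model).
#' @param ct_only if `TRUE`, also fit the simplified CT-only model
#'   (subarachnoid haemorrhage and finger-like projections, no genotype) and
#'   compare it with the full model.
#' @param exclude optional one-sided formula naming rows to exclude before
#'   analysis, e.g. `~ anticoagulant_use == 1` for the sensitivity analysis
#'   excluding anticoagulated participants.
#' @param bootstrap_B bootstrap replicates for internal validation.
#' @param seed integer seed for every stochastic stage.
#' @param dca_thresholds decision-curve threshold grid.
#' @param coefficients coefficient set used for the pattern profile table
#'   (`"fitted"` to use the fitted model, or a named numeric vector such as
#'   [default_coefficients()]).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = "fixture",
                            predictors = c("apoe_e4", "sah", "flp"),
                            ct_only = FALSE,
                            exclude = NULL,
                            bootstrap_B = 2000L,
                            seed = 1L,
                            dca_thresholds = seq(0.01, 0.99, by = 0.01),
                            coefficients = "fitted") {
  if (bootstrap_B < 1L) stop("bootstrap_B must be >= 1", call. = FALSE)
  if (length(predictors) == 0L) stop("predictor list must be non-empty",
                                     call. = FALSE)
  structure(list(input = input, predictors = predictors, ct_only = ct_only,
                 exclude = exclude, bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed), dca_thresholds = dca_thresholds,
                 coefficients = coefficients),
            class = "pipeline_config")
}

resolve_cohort <- function(input) {
  if (inherits(input, "caa_cohort")) return(input)
  if (inherits(input, "simulation_config")) return(simulate_cohort(input))
  if (identical(input, "fixture")) return(fixture_cohort())
  if (is.character(input) && length(input) == 1L)
    return(read_cohort_csv(input))
  stop("cannot resolve pipeline input", call. = FALSE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full diagnostic-model pipeline
#'
#' Sequence: resolve cohort (fixture / CSV / simulation), optional exclusion,
#' summary table, Firth model fit with Wald tests, profile CIs, VIFs and
#' model chi-square, apparent performance, bootstrap internal validation,
#' 8-pattern risk-profile table, per-participant criteria assignment,
#' diagnostic accuracy of the rule-in and rule-out criteria, decision curve.
#' Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return a `report_bundle` list; `manifest` records config, seed and
#'   package version.
#' @examples
#' \donttest{
#' bundle <- run_pipeline(pipeline_config(bootstrap_B = 50))
#' bundle$accuracy$rule_out$sensitivity
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- stage("input", resolve_cohort(config$input))
  n_removed <- 0L
  if (!is.null(config$exclude)) {
    cohort <- stage("exclude", {
      expr <- if (inherits(config$exclude, "formula"))
        config$exclude[[2]] else config$exclude
      out <- eval(bquote(filter_cohort(cohort, .(expr))))
      out
    })
    n_removed <- attr(cohort, "n_removed")
  }
  data <- as.data.frame(cohort)

  table1_vars <- c(
    apoe_e4 = "binary", apoe_e2 = "binary", sah = "binary", flp = "binary",
    anticoagulant_use = "binary", strictly_lobar = "binary",
    age_years = "continuous", ich_volume_ml = "continuous")
  table1_vars <- table1_vars[names(table1_vars) %in% names(data)]
  table1 <- stage("table1", build_table1(cohort, table1_vars))

  fit <- stage("fit", fit_firth(data, predictors = config$predictors))
  null_fit <- stage("fit", fit_firth(data, predictors = character(0)))
  model <- list(
    fit = fit,
    wald = wald_tests(fit),
    profile_ci = stage("profile_ci", profile_ci(fit)),
    vif = if (length(config$predictors) >= 2)
      compute_vif(data, predictors = config$predictors) else NULL,
    model_chi2 = plr_test(fit, null_fit))

  performance <- stage("performance", performance_metrics(fit))
  validation <- stage("validation", bootstrap_validate(
    cohort, predictors = config$predictors,
    B = config$bootstrap_B, seed = config$seed))

  coefs <- if (identical(config$coefficients, "fitted")) {
    stats::setNames(fit$coefficients,
                    c("intercept", config$predictors))
  } else config$coefficients
  has_pattern <- all(c("apoe_e4", "sah", "flp") %in% names(data))
  profiles <- if (has_pattern) enumerate_profiles(coefs) else NULL

  criteria <- NULL; accuracy <- NULL
  if (has_pattern) {
    pat <- data[c("apoe_e4", "sah", "flp")]
    criteria <- data.frame(
      id = data$id, outcome = data$outcome, pat,
      probability = predicted_probability(pat, coefs),
      category = classify_risk(pat),
      rule_out_negative = apply_rule_out(pat),
      rule_in_positive = apply_rule_in(pat))
    # rule-out: test positive = NOT ruled out (low vs medium/high split)
    ro_pos <- !criteria$rule_out_negative
    ri_pos <- criteria$rule_in_positive
    y <- data$outcome
    accuracy <- list(
      rule_out = accuracy_stats(c(sum(ro_pos & y == 1), sum(ro_pos & y == 0),
                                  sum(!ro_pos & y == 1), sum(!ro_pos & y == 0))),
      rule_in = accuracy_stats(c(sum(ri_pos & y == 1), sum(ri_pos & y == 0),
                                 sum(!ri_pos & y == 1), sum(!ri_pos & y == 0))))
  }

  ct_only <- NULL
  if (isTRUE(config$ct_only) && has_pattern) {
    ct_fit <- stage("ct_only", fit_firth(data, predictors = c("sah", "flp")))
    sah_pos <- data$sah == 1
    both_pos <- data$sah == 1 & data$flp == 1
    y <- data$outcome
    ct_only <- list(
      fit = ct_fit,
      wald = wald_tests(ct_fit),
      model_chi2 = plr_test(ct_fit, null_fit),
      comparison_vs_full = plr_test(fit, ct_fit),
      # CT-only criteria: rule out on absence of SAH; rule in on SAH + FLP
      rule_out = accuracy_stats(c(sum(sah_pos & y == 1), sum(sah_pos & y == 0),
                                  sum(!sah_pos & y == 1), sum(!sah_pos & y == 0))),
      rule_in = accuracy_stats(c(sum(both_pos & y == 1), sum(both_pos & y == 0),
                                 sum(!both_pos & y == 1), sum(!both_pos & y == 0))))
  }

  dca <- if (has_pattern)
    stage("dca", decision_curve(predicted_probability(
      data[c("apoe_e4", "sah", "flp")], coefs), data$outcome,
      config$dca_thresholds)) else NULL

  structure(list(
    cohort = cohort, table1 = table1, model = model, ct_only = ct_only,
    performance = performance, validation = validation,
    profiles = profiles, criteria = criteria, accuracy = accuracy,
    decision_curve = dca,
    manifest = list(
      config = unclass(config)[setdiff(names(config), "exclude")],
      excluded = n_removed, n = nrow(data),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("caadx")))
  ), class = "report_bundle")
}

bundle_sections <- c("cohort", "table1", "model", "performance",
                     "validation", "manifest")

#' Render a report bundle
#'
#' Formats follow the reporting conventions of the analysis: odds ratios to
#' 2 decimal places, percentages to the nearest integer, p-values to at most
#' 4 decimal places with a `"<0.0001"` floor.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param format `"markdown"` (single file), `"json"` (single file) or
#'   `"csv"` (a set of CSV tables).
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(bundle, format = c("markdown", "json", "csv"),
                          dir = ".") {
  format <- match.arg(format)
  stopifnot(inherits(bundle, "report_bundle"))
  missing_sections <- bundle_sections[!vapply(
    bundle_sections, function(s) !is.null(bundle[[s]]), logical(1))]
  if (length(missing_sections))
    stop("incomplete bundle; missing section(s): ",
         paste(missing_sections, collapse = ", "), call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (format == "markdown") {
    path <- file.path(dir, "report.md")
    writeLines(render_markdown(bundle), path)
    files <- path
  } else if (format == "json") {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(bundle_to_list(bundle), path, auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
    files <- path
  } else {
    w <- function(df, name) {
      p <- file.path(dir, paste0(name, ".csv"))
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    files <- c(
      w(bundle$table1, "table1"),
      w(bundle$model$wald, "model_coefficients"),
      if (!is.null(bundle$profiles)) w(bundle$profiles, "risk_profiles"),
      if (!is.null(bundle$criteria)) w(bundle$criteria, "criteria_assignments"),
      if (!is.null(bundle$decision_curve))
        w(as.data.frame(bundle$decision_curve), "decision_curve"),
      w(bundle$performance$roc, "roc_points"))
  }
  invisible(files)
}

accuracy_row <- function(name, acc) {
  sprintf("| %s | %d%% (%d–%d) | %d%% (%d–%d) | %s | %s |",
          name,
          round(100 * acc$sensitivity[["estimate"]]),
          round(100 * acc$sensitivity[["lower"]]),
          round(100 * acc$sensitivity[["upper"]]),
          round(100 * acc$specificity[["estimate"]]),
          round(100 * acc$specificity[["lower"]]),
          round(100 * acc$specificity[["upper"]]),
          if (is.finite(acc$lr_pos[["estimate"]]))
            sprintf("%.1f", acc$lr_pos[["estimate"]]) else "Inf",
          sprintf("%.2f", acc$lr_neg[["estimate"]]))
}

render_markdown <- function(bundle) {
  man <- bundle$manifest
  lines <- c(
    "# CAA-associated lobar ICH diagnostic model report",
    "",
    sprintf("n = %d participants (%d excluded), seed %d, caadx %s",
            man$n, man$excluded, man$seed, man$package_version),
    "",
    "## Group comparison",
    "",
    "| Variable | Absent/mild CAA | Moderate/severe CAA | OR (95% CI) | p |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s |",
            bundle$table1$variable, bundle$table1$group0,
            bundle$table1$group1, bundle$table1$or_display,
            fmt_p(bundle$table1$p)),
    "",
    "## Firth model",
    "",
    "| Term | beta (SE) | OR | p |",
    "|---|---|---|---|",
    sprintf("| %s | %.2f (%.2f) | %.2f | %s |",
            bundle$model$wald$term, bundle$model$wald$beta,
            bundle$model$wald$se, bundle$model$wald$odds_ratio,
            fmt_p(bundle$model$wald$p)),
    "",
    sprintf("Model chi-square %.1f (df %d, p %s); AIC %.1f",
            bundle$model$model_chi2$statistic, bundle$model$model_chi2$df,
            fmt_p(bundle$model$model_chi2$p), bundle$model$fit$aic),
    "",
    "## Performance (apparent / optimism-corrected)",
    "",
    sprintf("c statistic %.2f / %.2f; Nagelkerke R2 %.2f / %.2f; Brier %.2f / %.2f",
            bundle$validation$apparent[["c_statistic"]],
            bundle$validation$corrected[["c_statistic"]],
            bundle$validation$apparent[["nagelkerke_r2"]],
            bundle$validation$corrected[["nagelkerke_r2"]],
            bundle$validation$apparent[["brier"]],
            bundle$validation$corrected[["brier"]]),
    sprintf("Hosmer-Lemeshow p %s",
            fmt_p(bundle$performance$hosmer_lemeshow$p)))
  if (!is.null(bundle$accuracy)) {
    lines <- c(lines, "",
               "## Diagnostic criteria",
               "",
               "| Criteria | Sensitivity (95% CI) | Specificity (95% CI) | LR+ | LR- |",
               "|---|---|---|---|---|",
               accuracy_row("Rule out (no SAH, no e4): positive = not ruled out",
                            bundle$accuracy$rule_out),
               accuracy_row("Rule in (SAH + e4 or FLP)", bundle$accuracy$rule_in))
  }
  if (!is.null(bundle$ct_only)) {
    lines <- c(lines, "",
               "## Simplified CT-only model",
               "",
               accuracy_row("SAH alone (rule out)", bundle$ct_only$rule_out),
               accuracy_row("SAH + FLP (rule in)", bundle$ct_only$rule_in),
               sprintf("Full vs CT-only model: chi-square %.1f, p %s",
                       bundle$ct_only$comparison_vs_full$statistic,
                       fmt_p(bundle$ct_only$comparison_vs_full$p)))
  }
  if (!is.null(bundle$profiles)) {
    lines <- c(lines, "",
               "## Risk profiles",
               "",
               "| e4 | SAH | FLP | Probability | Category |",
               "|---|---|---|---|---|",
               sprintf("| %d | %d | %d | %d%% | %s |",
                       bundle$profiles$apoe_e4, bundle$profiles$sah,
                       bundle$profiles$flp,
                       round(100 * bundle$profiles$probability),
                       bundle$profiles$category))
  }
  lines
}

bundle_to_list <- function(bundle) {
  list(
    manifest = bundle$manifest,
    table1 = bundle$table1,
    model = list(
      coefficients = bundle$model$wald,
      profile_ci = bundle$model$profile_ci,
      vif = as.list(bundle$model$vif),
      model_chi2 = bundle$model$model_chi2,
      loglik_penalized = bundle$model$fit$loglik_penalized,
      loglik_unpenalized = bundle$model$fit$loglik_unpenalized,
      aic = bundle$model$fit$aic,
      converged = bundle$model$fit$converged,
      iterations = bundle$model$fit$iter),
    performance = list(
      nagelkerke_r2 = bundle$performance$nagelkerke_r2,
      brier = bundle$performance$brier,
      aic = bundle$performance$aic,
      c_statistic = bundle$performance$c_statistic,
      discrimination_slope = bundle$performance$discrimination_slope,
      hosmer_lemeshow = bundle$performance$hosmer_lemeshow),
    validation = list(
      apparent = as.list(bundle$validation$apparent),
      optimism = as.list(bundle$validation$optimism),
      corrected = as.list(bundle$validation$corrected),
      B = bundle$validation$B, n_failed = bundle$validation$n_failed),
    profiles = bundle$profiles,
    accuracy = if (!is.null(bundle$accuracy)) list(
      rule_out = unclass(bundle$accuracy$rule_out),
      rule_in = unclass(bundle$accuracy$rule_in)),
    ct_only = if (!is.null(bundle$ct_only)) list(
      coefficients = bundle$ct_only$wald,
      model_chi2 = bundle$ct_only$model_chi2,
      comparison_vs_full = bundle$ct_only$comparison_vs_full,
      rule_out = unclass(bundle$ct_only$rule_out),
      rule_in = unclass(bundle$ct_only$rule_in)),
    decision_curve = if (!is.null(bundle$decision_curve))
      as.data.frame(bundle$decision_curve))
}
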