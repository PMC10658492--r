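# End-to-end external-validation orchestration and report assembly.

#' Run the full external-validation workflow on a cohort
#'
#' Orchestrates the two-step validation of the prediction tool on a cohort
#' with adjudicated outcomes: (1) transportability - baseline table
#' stratified by outcome and refit of the model structure with a
#' development-vs-refit coefficient comparison; (2) performance - tool
#' scores and full-model predicted probabilities, logistic recalibration,
#' Hosmer-Lemeshow, calibration table by deciles, ROC curve and
#' c-statistic, and threshold diagnostics at the configured score
#' thresholds (defaults 2 and 0).
#'
#' @param cohort cohort data frame with an `outcome` column
#'   (see [read_cohort()]); for score-only output on cohorts without
#'   outcomes use [score_cohort()] / [predict_probability()].
#' @param thresholds integer score thresholds to evaluate, default `c(2, 0)`.
#' @param probability_source `"full_model"` (default) or `"score_lookup"`;
#'   the latter requires `lookup`.
#' @param lookup optional score-to-probability table for
#'   [score_to_probability()].
#' @param coefficients the embedded model, default
#'   `cushing_coefficients("development")`.
#' @param groups calibration/Hosmer-Lemeshow group count, default 10.
#' @param out_dir optional directory; when given, the report bundle is
#'   written there as delimited tables plus a machine-readable JSON summary
#'   and run manifest.
#' @param seed optional seed recorded in the manifest (the workflow itself
#'   is deterministic).
#' @return object of class `cushing_validation`: list with elements
#'   `scores`, `predicted`, `baseline`, `refit`, `coefficient_comparison`,
#'   `recalibration`, `hosmer_lemeshow`, `calibration`, `discrimination`,
#'   `roc`, `thresholds`, `manifest`.
#' @export
run_validation <- function(cohort, thresholds = c(2, 0),
                           probability_source = c("full_model", "score_lookup"),
                           lookup = NULL,
                           coefficients = cushing_coefficients("development"),
                           groups = 10, out_dir = NULL, seed = NULL) {
  probability_source <- match.arg(probability_source)
  if (!"outcome" %in% names(cohort)) {
    stop("cohort has no outcome column; use score_cohort() for score-only mode",
         call. = FALSE)
  }
  warnings_log <- character()
  stage <- function(label, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log, sprintf("[%s] %s", label, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }
  y <- cohort$outcome
  scores <- stage("scoring", score_cohort(cohort))
  predicted <- stage("prediction", {
    if (probability_source == "full_model") {
      predict_probability(cohort, coefficients)
    } else {
      if (is.null(lookup)) stop("score_lookup source requires a lookup table")
      score_to_probability(scores$total, lookup)
    }
  })
  baseline_vars <- c("neuter_status", "age_years", SIGN_FIELDS, "usg", "alp")
  baseline <- stage("casemix", baseline_table(cohort, baseline_vars, "outcome"))
  refit <- stage("refit", fit_logistic(cohort))
  comparison <- stage("refit", compare_coefficients(cushing_coefficients("development"), refit))
  recal <- stage("recalibration", recalibrate(predicted, y))
  hl <- stage("hosmer-lemeshow", hosmer_lemeshow(predicted, y, groups))
  caltab <- stage("calibration", calibration_table(predicted, y, groups))
  disc <- stage("discrimination", c_statistic(predicted, y))
  roc <- stage("discrimination", roc_curve(predicted, y))
  thr <- lapply(thresholds, function(t)
    stage("thresholds", threshold_diagnostics(scores$total, y, t)))
  names(thr) <- paste0("score_ge_", thresholds)
  manifest <- list(
    n = nrow(cohort), n_cases = sum(y == 1), n_noncases = sum(y == 0),
    thresholds = thresholds, probability_source = probability_source,
    groups = groups, seed = seed,
    package_version = as.character(packageVersion("cushval")),
    r_version = R.version.string, timestamp = format(Sys.time(), tz = "UTC"),
    warnings = warnings_log
  )
  res <- structure(list(scores = scores, predicted = predicted,
                        baseline = baseline, refit = refit,
                        coefficient_comparison = comparison,
                        recalibration = recal, hosmer_lemeshow = hl,
                        calibration = caltab, discrimination = disc, roc = roc,
                        thresholds = thr, manifest = manifest),
                   class = "cushing_validation")
  if (!is.null(out_dir)) write_validation_report(res, out_dir)
  res
}

#' @export
print.cushing_validation <- function(x, ...) {
  cat(sprintf("External validation of the Cushing's prediction tool (n = %d; %d cases, %d non-cases)\n\n",
              x$manifest$n, x$manifest$n_cases, x$manifest$n_noncases))
  print(x$recalibration)
  cat(sprintf("  Hosmer-Lemeshow chi-square = %.2f on %d df, P = %s\n",
              x$hosmer_lemeshow$statistic, x$hosmer_lemeshow$df,
              format_pvalue(x$hosmer_lemeshow$p)))
  print(x$discrimination)
  for (t in x$thresholds) print(t)
  if (length(x$refit$separation)) {
    cat("Separation flagged when refitting:",
        paste(x$refit$separation, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a validation report bundle to disk
#'
#' Emits the calibration table, ROC points, coefficient comparison and
#' baseline table as delimited files, plus `summary.json` (the headline
#' statistics) and `manifest.json` (inputs, options, versions, collected
#' warnings) for machine consumption.
#'
#' @param result a `cushing_validation` object.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_validation_report <- function(result, out_dir) {
  stopifnot(inherits(result, "cushing_validation"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) write.table(df, file.path(out_dir, name), sep = "\t",
                                       row.names = FALSE, quote = FALSE)
  wt(result$calibration, "calibration_deciles.tsv")
  wt(result$roc, "roc_points.tsv")
  wt(result$coefficient_comparison, "coefficient_comparison.tsv")
  wt(result$baseline, "baseline_table.tsv")
  summary <- list(
    a = result$recalibration$a$estimate,
    a_ci = result$recalibration$a$ci,
    a_p = result$recalibration$a$p,
    b = result$recalibration$b$estimate,
    b_ci = result$recalibration$b$ci %||% NULL,
    b_p_vs_0 = result$recalibration$b$p %||% NULL,
    b_p_vs_1 = result$recalibration$b_vs_1$p %||% NULL,
    hosmer_lemeshow = result$hosmer_lemeshow[c("statistic", "df", "p")],
    c_statistic = result$discrimination$c_statistic,
    c_ci = result$discrimination$ci,
    band = result$discrimination$band,
    thresholds = lapply(result$thresholds, function(t)
      t[c("threshold", "tp", "fp", "tn", "fn",
          "sensitivity", "specificity", "ppv", "npv")])
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
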