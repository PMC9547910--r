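#' Run the full validation + cost pipeline on a data bundle
#'
#' End-to-end orchestration: scores the GCPS questionnaire, classifies the
#' chronicity class from claims, builds the selection cascade (cost cohort,
#' validation cohort, sick-leave-insured subgroup), computes the
#' criterion-validity metric reports for the validation cohort and the
#' subgroup, and summarises CPI-adjusted 12-month costs by GCPS grade over
#' the cost cohort.
#'
#' @param data Named list of tables as returned by [read_claims_tables()]
#'   or [generate_population()].
#' @param cc_cfg Classifier configuration ([cc_config()]).
#' @param cpi_table,base_year Price adjustment for the cost stage.
#' @param kappa_weights Weighting for the 3 x 3 kappa.
#' @return List of class `chronicity_results`: `gcps_scores`, `cc_classes`,
#'   `cohorts` (with cascade `ledger`), `validation` (a
#'   [validity_report()]), `validation_sickleave` (subgroup report, `NULL`
#'   if the subgroup is empty), `cost_table`, `descriptives` (counts and
#'   score means by grade).
#' @export
run_pipeline <- function(data, cc_cfg = cc_config(),
                         cpi_table = default_cpi_table(),
                         base_year = 2020L, kappa_weights = "linear") {
  for (tbl in c("enrolment", "gcps_items")) {
    if (is.null(data[[tbl]])) {
      abort(paste0("stage 'input': required table '", tbl, "' is missing"))
    }
  }
  scores <- score_gcps(data$gcps_items)
  cc_classes <- classify_cc(data, cc_cfg)
  sel <- select_cohorts(data$enrolment, data$invoices,
                        window_days = 365L, max_enrol_days = 90L)

  joined <- dplyr::inner_join(scores, cc_classes[, c("person_id", "cc")],
                              by = "person_id")
  val_ids <- sel$cohorts$validation_cohort
  vdat <- joined[joined$person_id %in% val_ids &
                   joined$cc != "not_classifiable", , drop = FALSE]
  if (nrow(vdat) == 0) abort("stage 'validation': validation cohort is empty")
  validation <- validity_report(droplevels(vdat$cc), vdat$grade3,
                                kappa_weights = kappa_weights)
  sub_ids <- sel$cohorts$sickleave_subgroup
  sdat <- vdat[vdat$person_id %in% sub_ids, , drop = FALSE]
  validation_sickleave <- if (nrow(sdat) >= 10)
    validity_report(droplevels(sdat$cc), sdat$grade3,
                    kappa_weights = kappa_weights) else NULL

  cost_table <- NULL
  if (!is.null(data$invoices)) {
    costs <- aggregate_costs(data$invoices, data$enrolment,
                             cpi_table = cpi_table, base_year = base_year)
    cost_ids <- sel$cohorts$cost_cohort
    groups <- tibble(person_id = scores$person_id,
                     group = paste0("GCPS_", scores$grade))
    cost_table <- cost_table_by_group(
      costs[costs$person_id %in% cost_ids, , drop = FALSE], groups)
  }

  descr <- scores |>
    dplyr::filter(.data$person_id %in% sel$cohorts$cost_cohort) |>
    dplyr::group_by(.data$grade) |>
    dplyr::summarise(n = dplyr::n(),
                     pct = NA_real_,
                     mean_pain_intensity = mean(.data$pain_intensity),
                     mean_disability_score = mean(.data$disability_score),
                     mean_disability_points = mean(.data$disability_points),
                     .groups = "drop")
  descr$pct <- 100 * descr$n / sum(descr$n)

  structure(
    list(gcps_scores = scores, cc_classes = cc_classes, cohorts = sel,
         validation = validation,
         validation_sickleave = validation_sickleave,
         cost_table = cost_table, descriptives = descr),
    class = "chronicity_results"
  )
}

#' @export
print.chronicity_results <- function(x, ...) {
  cat("Chronicity validation pipeline results\n")
  cat("Cohort cascade:\n")
  print(x$cohorts$ledger)
  cat("\nValidation cohort:\n")
  print(x$validation)
  if (!is.null(x$validation_sickleave)) {
    cat("\nSick-leave-insured subgroup:\n")
    print(x$validation_sickleave)
  }
  invisible(x)
}

#' Write the pipeline outputs to disk
#'
#' Emits `gcps_scores.csv`, `cc_classes.csv`, `cohort_ledger.json`,
#' `metrics.json` (2 x 2 and 3 x 3 metrics with confidence intervals and
#' verbal bands), `cost_summary.csv` and the rendered confusion report
#' `validation_report.txt`.
#'
#' @param results A `chronicity_results` object from [run_pipeline()].
#' @param dir Output directory, created if absent.
#' @return Invisibly, the vector of files written.
#' @export
write_pipeline_outputs <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_csv(df, path, progress = FALSE)
    files <<- c(files, path)
  }
  wr(results$gcps_scores, "gcps_scores.csv")
  wr(results$cc_classes, "cc_classes.csv")
  if (!is.null(results$cost_table)) wr(results$cost_table, "cost_summary.csv")
  jsonlite::write_json(results$cohorts$ledger,
                       file.path(dir, "cohort_ledger.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, file.path(dir, "cohort_ledger.json"))
  rep_json <- function(v) {
    list(
      n = v$n,
      rho = list(estimate = v$rho$estimate, conf_int = v$rho$conf_int,
                 band = interpret_metric("rho", v$rho$estimate)),
      kappa3 = list(estimate = v$kappa3$estimate,
                    conf_int = v$kappa3$conf_int,
                    weights = v$kappa3$weights,
                    band = interpret_metric("kappa", v$kappa3$estimate)),
      matrix2 = list(labels = v$matrix2$labels,
                     counts = unclass(v$matrix2$counts)),
      sensitivity = v$sensitivity, specificity = v$specificity,
      correct = v$correct,
      mcc = list(estimate = v$mcc, band = interpret_metric("mcc", v$mcc)),
      kappa2 = list(estimate = v$kappa2$estimate,
                    conf_int = v$kappa2$conf_int,
                    band = interpret_metric("kappa", v$kappa2$estimate))
    )
  }
  metrics <- list(validation = rep_json(results$validation))
  if (!is.null(results$validation_sickleave)) {
    metrics$validation_sickleave <- rep_json(results$validation_sickleave)
  }
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, file.path(dir, "metrics.json"))
  writeLines(render_confusion_report(results$validation$matrix2),
             file.path(dir, "validation_report.txt"))
  files <- c(files, file.path(dir, "validation_report.txt"))
  invisible(files)
}
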