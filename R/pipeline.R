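#' Overall treatment-duration records from second-line start
#'
#' One survival record per patient with a second line: duration from the
#' start of second-line therapy to the last antitumor expected final dose
#' date across all subsequent lines; the event indicator follows the
#' 60-day completion rule (60 days or more of data after the expected final
#' dose), otherwise the record is censored at the expected final dose date.
#'
#' @param lines derived lines.
#' @param bundle the `claims_bundle`.
#' @return tibble with `patient_id`, `duration_days`, `event`.
#' @export
overall_duration_records <- function(lines, bundle) {
  data_end <- setNames(bundle$patients$data_end, bundle$patients$patient_id)
  lines[lines$line_number >= 2L, ] |>
    dplyr::summarise(
      start2 = min(.data$start_date),
      final_efd = max(.data$expected_final_dose_date),
      .by = "patient_id") |>
    dplyr::mutate(
      duration_days = days_between(.data$start2, .data$final_efd),
      event = days_between(.data$final_efd, data_end[.data$patient_id]) >= 60L) |>
    dplyr::select("patient_id", "duration_days", "event")
}

flatten_lines <- function(lines) {
  lines |>
    dplyr::mutate(
      base_drugs = purrr::map_chr(.data$base_drugs, paste, collapse = ";"),
      all_drugs = purrr::map_chr(.data$all_drugs, paste, collapse = ";"),
      additions = purrr::map_chr(.data$additions, function(a) {
        if (nrow(a) == 0) "" else paste(a$drug_id, a$date, sep = ":", collapse = ";")
      }))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

#' Run the whole analysis pipeline
#'
#' Orchestrates cohort selection, line derivation, sequence metrics and the
#' statistical stages over a claims bundle (read from disk, passed
#' in-memory, or simulated), and writes the output tables plus a run
#' manifest to `out_dir`. Any stage failure halts with the stage name and
#' cause. Reruns on identical inputs and seed reproduce identical outputs
#' (the manifest timestamp aside).
#'
#' @param out_dir output directory (created if needed).
#' @param bundle an in-memory `claims_bundle`, or `NULL`.
#' @param bundle_dir directory to read a bundle from, or `NULL`.
#' @param sim a [sim_config()] to simulate a bundle, or `NULL`; exactly one
#'   bundle source must be given.
#' @param seed seed recorded in the manifest and used for simulation.
#' @param cohort a [cohort_config()].
#' @param vocab vocabulary table.
#' @return invisibly, a list with every intermediate result (`bundle`,
#'   `cohorts`, `lines`, `rates`, `sequences`, `second_line`, `covariates`,
#'   `km`, `logistic`, `cox`, `manifest`).
#' @export
run_pipeline <- function(out_dir, bundle = NULL, bundle_dir = NULL, sim = NULL,
                         seed = NULL, cohort = cohort_config(),
                         vocab = drug_vocabulary()) {
  sources <- sum(!is.null(bundle), !is.null(bundle_dir), !is.null(sim))
  if (sources != 1) abort("give exactly one of bundle, bundle_dir or sim")
  truth <- NULL
  if (!is.null(bundle_dir)) {
    if (!dir.exists(bundle_dir)) abort(paste0("bundle directory not found: ", bundle_dir))
    bundle <- run_stage("read_bundle", read_bundle(bundle_dir))
  } else if (!is.null(sim)) {
    simulated <- run_stage("simulate", simulate_bundle(sim, seed = seed))
    bundle <- simulated$bundle
    truth <- simulated$truth
  }

  cohorts_res <- run_stage("cohorts", select_cohorts(bundle, cohort, vocab))
  members <- cohorts_res$members
  lines <- run_stage("lines", derive_lines_bundle(bundle, members, vocab))
  members <- run_stage("index_dates", assign_index_dates(members, lines))
  members <- run_stage("subpopulation",
                       select_folfiri_aa_subpopulation(members, lines, bundle, vocab))

  rates <- run_stage("transition_rates", transition_rates(lines, members))
  sequences <- run_stage("sequence_table", sequence_table(lines, members, vocab = vocab))
  second_line <- run_stage("second_line_report",
                           second_line_aa_report(lines, members, bundle))

  subpop <- members[members$in_folfiri_aa_subpop %in% TRUE, ]
  covariates <- km <- logistic <- cox <- NULL
  if (nrow(subpop) > 0) {
    covariates <- run_stage("covariates", build_covariates(bundle, subpop, lines, vocab))
    detail <- second_line$patients[match(subpop$patient_id, second_line$patients$patient_id), ]
    km <- run_stage("km", km_duration(detail))
    logistic <- run_stage("logistic",
                          fit_single_dose_logistic(covariates, detail$single_use))
    duration <- run_stage("duration_records", overall_duration_records(lines, bundle))
    duration <- duration[match(subpop$patient_id, duration$patient_id), ]
    cox <- run_stage("cox", fit_overall_duration_cox(covariates, duration))
  }

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- list(
    "cohorts.csv" = members,
    "selection_log_first_line.csv" = cohorts_res$logs$first_line,
    "selection_log_early_recurrence.csv" = cohorts_res$logs$early_recurrence,
    "lines.csv" = flatten_lines(lines),
    "transition_rates.csv" = rates,
    "sequence_regimens.csv" = sequences$regimens,
    "sequence_flows.csv" = sequences$flows,
    "second_line_report.csv" = second_line$report,
    "second_line_patients.csv" = second_line$patients)
  if (!is.null(km)) outputs[["km_summary.csv"]] <- glance(km)
  if (!is.null(km)) outputs[["km_curve.csv"]] <- tidy(km)
  if (!is.null(logistic)) outputs[["logistic_model.csv"]] <- tidy(logistic)
  if (!is.null(cox)) outputs[["cox_model.csv"]] <- tidy(cox)
  for (nm in names(outputs)) {
    readr::write_csv(outputs[[nm]], file.path(out_dir, nm), progress = FALSE, na = "")
  }

  manifest <- list(
    seed = seed %||% (if (!is.null(sim)) sim$seed else NA),
    config_hash = rlang::hash(list(cohort = unclass(cohort),
                                   sim = if (!is.null(sim)) unclass(sim))),
    package_version = as.character(utils::packageVersion("crclot")),
    row_counts = c(list(patients = nrow(bundle$patients)),
                   purrr::map(outputs, nrow)),
    outputs = names(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(bundle = bundle, truth = truth, cohorts = members,
                 selection_logs = cohorts_res$logs, lines = lines,
                 rates = rates, sequences = sequences, second_line = second_line,
                 covariates = covariates, km = km, logistic = logistic, cox = cox,
                 manifest = manifest, out_dir = out_dir))
}

n_pct <- function(n, d) {
  ifelse(is.na(rate_percent(n, d)), sprintf("%d (-)", n),
         sprintf("%d (%.1f)", n, rate_percent(n, d)))
}

#' Render paper-shaped summary tables
#'
#' Formats pipeline results as the three report tables: transition rates
#' with RAS strata as columns, the second-line antiangiogenic prescription
#' summary with n (%) cells, and the model estimate tables (odds/hazard
#' ratio, 95% CI, p-value). Also writes a plain-text rendering when
#' `out_dir` is given.
#'
#' @param results list returned by [run_pipeline()].
#' @param out_dir optional directory for `report.txt`.
#' @return list of formatted tibbles (`transition_rates`, `second_line`,
#'   `logistic`, `cox`).
#' @export
render_tables <- function(results, out_dir = NULL) {
  for (nm in c("rates", "second_line")) {
    if (is.null(results[[nm]])) abort(paste0("render_tables: missing input '", nm, "'"))
  }
  rates <- results$rates
  t1 <- rates |>
    dplyr::mutate(cell = n_pct(.data$n_transitioned, .data$n_evaluable),
                  transition = paste0(.data$from_line, " to ", .data$to_line)) |>
    dplyr::select("population", "transition", "presumed_ras", "cell",
                  "n_evaluable") |>
    tidyr::pivot_wider(names_from = "presumed_ras",
                       values_from = c("cell", "n_evaluable"))

  rep <- results$second_line$report
  t3 <- if (nrow(rep) == 0) {
    tibble::tibble(variable = "patients in subpopulation", overall = "0")
  } else {
    long <- rep |>
      dplyr::transmute(
        stratum = .data$stratum,
        `patients in subpopulation` = as.character(.data$n_subpop),
        `evaluable patients` = as.character(.data$n_evaluable),
        `transitioned to 3rd line, n (%)` = n_pct(.data$n_transitioned_3rd, .data$n_evaluable),
        `antiangiogenic prescriptions, median (IQR)` =
          sprintf("%.0f (%.0f-%.0f)", .data$median_aa_prescriptions,
                  .data$iqr_low, .data$iqr_high),
        `dose reductions, n (%)` = n_pct(.data$n_dose_reduced, .data$n_evaluable),
        `prescription gaps >=21 days, n (%)` = n_pct(.data$n_gap_ge21, .data$n_evaluable),
        `single antiangiogenic use, n (%)` = n_pct(.data$n_single_use, .data$n_evaluable))
    tidyr::pivot_longer(long, -"stratum", names_to = "variable") |>
      tidyr::pivot_wider(names_from = "stratum", values_from = "value")
  }

  fmt_model <- function(fit) {
    if (is.null(fit)) return(NULL)
    tidy(fit) |>
      dplyr::mutate(
        estimate = sprintf("%.2f", .data$estimate),
        `95% CI` = sprintf("%.2f-%.2f", .data$conf_low, .data$conf_high),
        `p-value` = ifelse(.data$p_value < 1e-4, "<0.0001",
                           sprintf("%.4f", .data$p_value))) |>
      dplyr::select("term", "estimate", "95% CI", "p-value")
  }
  tables <- list(transition_rates = t1, second_line = t3,
                 logistic = fmt_model(results$logistic),
                 cox = fmt_model(results$cox))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    txt <- character()
    for (nm in names(tables)) {
      if (is.null(tables[[nm]])) next
      txt <- c(txt, paste0("== ", nm, " =="),
               utils::capture.output(print(as.data.frame(tables[[nm]]), row.names = FALSE)), "")
    }
    writeLines(txt, file.path(out_dir, "report.txt"))
  }
  tables
}
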