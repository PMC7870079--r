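#' Transition rates between lines of therapy
#'
#' For each stratum (population x presumed RAS status) and each consecutive
#' line pair, counts patients evaluable for transition (next line observed,
#' or more than 60 days of data after the line end, so that non-transition
#' is observable) and those with an observed next line. The adjuvant to
#' second-line pair is excluded for the early-recurrence population, where
#' it is 100% by definition. Rates are percentages rounded half-up to one
#' decimal; a stratum with zero evaluable patients reports `NA`, never 0.
#'
#' @param lines derived lines from [derive_lines_bundle()].
#' @param cohorts cohort members tibble (for population / RAS strata).
#' @return tibble: `population`, `presumed_ras`, `from_line`, `to_line`,
#'   `n_evaluable`, `n_transitioned`, `rate_percent`.
#' @export
transition_rates <- function(lines, cohorts) {
  joined <- dplyr::inner_join(
    lines, cohorts[, c("patient_id", "population", "presumed_ras")],
    by = "patient_id")
  out <- joined |>
    dplyr::filter(.data$evaluable_for_transition) |>
    dplyr::filter(!(.data$population == "early_recurrence" & .data$line_number == 0L)) |>
    dplyr::summarise(
      n_evaluable = dplyr::n(),
      n_transitioned = sum(.data$transitioned),
      .by = c("population", "presumed_ras", "line_number")) |>
    dplyr::mutate(
      from_line = line_label(.data$line_number),
      to_line = as.character(ifelse(.data$line_number == 0L, 2L, .data$line_number + 1L)),
      rate_percent = rate_percent(.data$n_transitioned, .data$n_evaluable)) |>
    dplyr::arrange(.data$population, .data$presumed_ras, .data$line_number)
  out[, c("population", "presumed_ras", "from_line", "to_line",
          "n_evaluable", "n_transitioned", "rate_percent")]
}

#' Regimen frequency tables and group-to-group flows per line
#'
#' Counts regimen labels per line number and stratum (sorted descending),
#' and summarises consecutive-line transitions between major regimen groups
#' (oxaliplatin-based, irinotecan-based, the combined
#' oxaliplatin+irinotecan group, fluoropyrimidine monotherapy, other) — the
#' tabular equivalent of a treatment-sequence flow diagram.
#'
#' @param lines derived lines.
#' @param cohorts cohort members.
#' @param max_line highest line number tabulated (default 3).
#' @param vocab vocabulary table.
#' @return list with `regimens` (label counts) and `flows` (from-group /
#'   to-group counts between consecutive lines).
#' @export
sequence_table <- function(lines, cohorts, max_line = 3L, vocab = drug_vocabulary()) {
  joined <- dplyr::inner_join(
    lines, cohorts[, c("patient_id", "population", "presumed_ras")],
    by = "patient_id") |>
    dplyr::filter(.data$line_number <= max_line)
  joined$regimen_group <- regimen_group(joined$base_drugs, vocab)

  regimens <- joined |>
    dplyr::summarise(n = dplyr::n(),
                     .by = c("population", "presumed_ras", "line_number",
                             "line_label", "regimen_label")) |>
    dplyr::arrange(.data$population, .data$presumed_ras, .data$line_number,
                   dplyr::desc(.data$n), .data$regimen_label)

  flows <- joined |>
    dplyr::arrange(.data$patient_id, .data$line_number) |>
    dplyr::mutate(
      next_group = dplyr::lead(.data$regimen_group),
      next_line = dplyr::lead(.data$line_number),
      .by = "patient_id") |>
    dplyr::filter(!is.na(.data$next_group),
                  .data$next_line == ifelse(.data$line_number == 0L, 2L,
                                            .data$line_number + 1L)) |>
    dplyr::summarise(n = dplyr::n(),
                     .by = c("population", "presumed_ras", "line_number",
                             "line_label", "regimen_group", "next_group")) |>
    dplyr::rename(from_group = "regimen_group", to_group = "next_group") |>
    dplyr::arrange(.data$population, .data$presumed_ras, .data$line_number,
                   dplyr::desc(.data$n))
  list(regimens = regimens, flows = flows)
}

second_line_aa_patient_detail <- function(lines, cohorts, prescriptions, data_end) {
  subpop <- cohorts[cohorts$in_folfiri_aa_subpop %in% TRUE, ]
  second <- lines[lines$line_number == 2L, ]
  third_exists <- unique(lines$patient_id[lines$line_number == 3L])
  purrr::map(seq_len(nrow(subpop)), function(i) {
    pid <- subpop$patient_id[i]
    row <- second[second$patient_id == pid, ]
    if (nrow(row) == 0) return(NULL)
    aa <- prescriptions[prescriptions$patient_id == pid &
                          prescriptions$drug_id %in% ANTIANGIOGENIC_DRUGS &
                          prescriptions$date >= row$start_date &
                          prescriptions$date < row$end_date, ]
    aa <- aa[order(aa$date), ]
    gaps <- if (nrow(aa) >= 2) diff(as.numeric(aa$date)) else numeric()
    # dose reduction: a same-drug prescription strictly below its immediate
    # predecessor, both doses present
    reduced <- any(vapply(split(aa, aa$drug_id), function(d) {
      ok <- !is.na(d$dose)
      any(diff(d$dose[ok]) < 0)
    }, logical(1)))
    aa_efd <- suppressWarnings(max(expected_final_dose_date(aa)))
    de <- data_end[[pid]]
    has_third <- pid %in% third_exists
    tibble::tibble(
      patient_id = pid,
      second_line_aa_drug = subpop$second_line_aa_drug[i],
      n_aa_prescriptions = nrow(aa),
      single_use = nrow(aa) == 1,
      gap_ge21 = length(gaps) > 0 && any(gaps >= 21),
      dose_reduced = reduced,
      evaluable = row$evaluable_for_transition,
      transitioned_3rd = has_third,
      duration_days = days_between(row$start_date, aa_efd),
      event = has_third || days_between(aa_efd, de) >= 60L)
  }) |> dplyr::bind_rows()
}

#' Second-line antiangiogenic prescription report
#'
#' Prescription characteristics and treatment continuation within the
#' second-line FOLFIRI plus antiangiogenic subpopulation, overall and per
#' antiangiogenic drug: antiangiogenic prescription counts (median, IQR),
#' dose reductions (a same-drug prescription with a strictly lower dose
#' than its immediate predecessor), prescription gaps of 21 days or more
#' (a >= 7-day delay against the biweekly schedule), single-prescription
#' use, and the transition rate to third-line therapy among evaluable
#' patients. Percentages of prescription characteristics use the evaluable
#' denominator, matching the reporting convention.
#'
#' @param lines derived lines.
#' @param cohorts cohort members with the subpopulation flags filled.
#' @param bundle the `claims_bundle`.
#' @return list with `report` (one row per stratum: `overall` plus each
#'   drug) and `patients` (the per-patient detail behind it, including the
#'   Kaplan-Meier duration records: `duration_days` from second-line start
#'   to the last antiangiogenic expected final dose, `event` = completed).
#' @export
second_line_aa_report <- function(lines, cohorts, bundle) {
  data_end <- setNames(bundle$patients$data_end, bundle$patients$patient_id)
  detail <- second_line_aa_patient_detail(lines, cohorts, bundle$prescriptions, data_end)
  if (nrow(detail) == 0) {
    return(list(report = tibble::tibble(
      stratum = character(), n_subpop = integer(), n_evaluable = integer(),
      n_transitioned_3rd = integer(), transition_rate_percent = numeric(),
      median_aa_prescriptions = numeric(), iqr_low = numeric(), iqr_high = numeric(),
      n_dose_reduced = integer(), pct_dose_reduced = numeric(),
      n_gap_ge21 = integer(), pct_gap_ge21 = numeric(),
      n_single_use = integer(), pct_single_use = numeric()),
      patients = detail))
  }
  summarise_stratum <- function(d, label) {
    ev <- d[d$evaluable, ]
    tibble::tibble(
      stratum = label,
      n_subpop = nrow(d),
      n_evaluable = nrow(ev),
      n_transitioned_3rd = sum(ev$transitioned_3rd),
      transition_rate_percent = rate_percent(sum(ev$transitioned_3rd), nrow(ev)),
      median_aa_prescriptions = stats::median(d$n_aa_prescriptions),
      iqr_low = unname(stats::quantile(d$n_aa_prescriptions, 0.25)),
      iqr_high = unname(stats::quantile(d$n_aa_prescriptions, 0.75)),
      n_dose_reduced = sum(ev$dose_reduced),
      pct_dose_reduced = rate_percent(sum(ev$dose_reduced), nrow(ev)),
      n_gap_ge21 = sum(ev$gap_ge21),
      pct_gap_ge21 = rate_percent(sum(ev$gap_ge21), nrow(ev)),
      n_single_use = sum(ev$single_use),
      pct_single_use = rate_percent(sum(ev$single_use), nrow(ev)))
  }
  report <- dplyr::bind_rows(
    summarise_stratum(detail, "overall"),
    dplyr::bind_rows(purrr::map(
      intersect(ANTIANGIOGENIC_DRUGS, unique(detail$second_line_aa_drug)),
      function(d) summarise_stratum(detail[detail$second_line_aa_drug == d, ], d))))
  list(report = report, patients = detail)
}
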