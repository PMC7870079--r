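#' Cohort selection configuration
#'
#' Calendar windows and day-count rules for cohort selection. Defaults are
#' the study conditions the pipeline emulates: confirmed colorectal cancer
#' diagnoses accepted between May 2014 and July 2019, enrollment (start of
#' first-line or adjuvant therapy) from May 2016, analysis period through
#' September 2019. Month-based windows use fixed day counts: 3 months = 91
#' days, 6 months = 183 days, 1 year = 365 days.
#'
#' @param diagnosis_window two dates bounding acceptable first diagnoses
#'   (and the qualifying anchor prescription/surgery).
#' @param enrollment_start earliest accepted therapy start date.
#' @param analysis_window two dates bounding the whole analysis period
#'   (used by the presumed-RAS rule).
#' @param washout_days monoclonal-antibody washout before the first-line
#'   anchor (prescriptions in `[anchor - washout_days, anchor - 1]` exclude).
#' @param adjuvant_window_days maximum days from resection to adjuvant start.
#' @param switch_window_days maximum days from the last adjuvant dose's
#'   expected final dose date to the start of second-line therapy.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(diagnosis_window = as.Date(c("2014-05-01", "2019-07-31")),
                          enrollment_start = as.Date("2016-05-01"),
                          analysis_window = as.Date(c("2014-05-01", "2019-09-30")),
                          washout_days = 365L,
                          adjuvant_window_days = 91L,
                          switch_window_days = 183L) {
  structure(list(diagnosis_window = as_iso_date(diagnosis_window),
                 enrollment_start = as_iso_date(enrollment_start),
                 analysis_window = as_iso_date(analysis_window),
                 washout_days = as.integer(washout_days),
                 adjuvant_window_days = as.integer(adjuvant_window_days),
                 switch_window_days = as.integer(switch_window_days)),
            class = "cohort_config")
}

#' First confirmed colorectal cancer diagnosis date
#'
#' Earliest confirmed diagnosis with ICD-10 prefix C18, C19 or C20 inside
#' the configured diagnosis window; `NA` if none. Rule-out diagnoses
#' (`confirmed = FALSE`) never qualify.
#'
#' @param bundle a `claims_bundle`.
#' @param patient_id one patient id.
#' @param config a [cohort_config()].
#' @return a `Date` (or `NA`).
#' @export
first_crc_diagnosis <- function(bundle, patient_id, config = cohort_config()) {
  dates <- crc_diagnosis_dates(bundle, config)
  d <- dates$date[dates$patient_id == patient_id]
  if (length(d) == 0) as.Date(NA) else min(d)
}

crc_diagnosis_dates <- function(bundle, config) {
  dx <- bundle$diagnoses
  keep <- dx$confirmed &
    grepl("^C(18|19|20)", dx$icd10) &
    dx$date >= config$diagnosis_window[1] &
    dx$date <= config$diagnosis_window[2]
  dx[keep, c("patient_id", "date")]
}

first_crc_dx_by_patient <- function(bundle, config) {
  crc_diagnosis_dates(bundle, config) |>
    dplyr::summarise(dx_date = min_date(.data$date), .by = "patient_id")
}

# patients with any prescription of an antitumor drug outside the
# treatment-guideline list (vocabulary class "other" with is_antitumor)
non_guideline_drug_patients <- function(bundle, vocab) {
  off_list <- vocab$drug_id[vocab$is_antitumor & vocab$drug_class == "other"]
  unique(bundle$prescriptions$patient_id[bundle$prescriptions$drug_id %in% off_list])
}

new_selection_log <- function(criterion, n_remaining) {
  tibble::tibble(criterion = criterion, n_remaining = n_remaining)
}

empty_members <- function() {
  tibble::tibble(
    patient_id = character(), population = character(),
    anchor_date = as.Date(character()), therapy_start_date = as.Date(character()),
    index_date = as.Date(character()), presumed_ras = character(),
    in_folfiri_aa_subpop = logical(), second_line_aa_drug = character(),
    multi_aa = logical()
  )
}

#' Presumed RAS status from anti-EGFR antibody use
#'
#' RAS mutation status is not recorded in claims; because anti-EGFR
#' antibodies are only recommended for RAS-wild-type disease, a patient with
#' at least one cetuximab or panitumumab prescription anywhere in the
#' analysis window is presumed `wild_type`, otherwise `mutant`.
#'
#' @param bundle a `claims_bundle`.
#' @param patient_id character vector of patient ids.
#' @param analysis_window two dates bounding the analysis period.
#' @return character vector (`"wild_type"`/`"mutant"`) per patient.
#' @export
presume_ras_status <- function(bundle, patient_id,
                               analysis_window = cohort_config()$analysis_window) {
  rx <- bundle$prescriptions
  egfr <- rx$patient_id[rx$drug_id %in% ANTI_EGFR_DRUGS &
                          rx$date >= analysis_window[1] &
                          rx$date <= analysis_window[2]]
  ifelse(patient_id %in% egfr, "wild_type", "mutant")
}

# Early-recurrence eligibility evaluated for every patient; returns members
# plus a criterion log. `apply_enrollment` lets the first-line selection ask
# "eligible at all?" before the enrollment-date filter is applied.
early_recurrence_candidates <- function(bundle, config, vocab, apply_enrollment = TRUE) {
  log <- new_selection_log("patients in bundle", nrow(bundle$patients))
  note <- function(lab, ids) log <<- dplyr::bind_rows(log, new_selection_log(lab, length(ids)))

  dx <- first_crc_dx_by_patient(bundle, config)
  note("confirmed CRC (C18-C20) diagnosis in window", dx$patient_id)

  surg <- bundle$procedures |>
    dplyr::filter(.data$kind == "colorectal_resection") |>
    dplyr::inner_join(dx, by = "patient_id") |>
    dplyr::filter(.data$date >= .data$dx_date,
                  .data$date >= config$diagnosis_window[1],
                  .data$date <= config$diagnosis_window[2]) |>
    dplyr::summarise(surgery_date = min_date(.data$date), dx_date = dplyr::first(.data$dx_date),
                     .by = "patient_id")
  note("colorectal resection after first CRC diagnosis", surg$patient_id)

  pat <- bundle$patients[match(surg$patient_id, bundle$patients$patient_id), ]
  surg <- surg[age_at(pat$birth_year, surg$surgery_date) >= 20L, ]
  note("age >= 20 at first resection", surg$patient_id)

  rx <- bundle$prescriptions
  adj <- rx[rx$drug_id %in% ADJUVANT_DRUGS, c("patient_id", "date")] |>
    dplyr::inner_join(surg, by = "patient_id") |>
    dplyr::filter(.data$date >= .data$surgery_date,
                  .data$date <= .data$surgery_date + config$adjuvant_window_days) |>
    dplyr::summarise(adjuvant_start = min_date(.data$date),
                     surgery_date = dplyr::first(.data$surgery_date),
                     .by = "patient_id")
  note("adjuvant therapy within 3 months of surgery", adj$patient_id)

  mab <- rx[rx$drug_id %in% FIRST_LINE_MABS, c("patient_id", "date")]
  biologic_before <- mab |>
    dplyr::inner_join(adj[c("patient_id", "surgery_date")], by = "patient_id") |>
    dplyr::filter(.data$date < .data$surgery_date) |>
    dplyr::pull("patient_id") |> unique()
  adj <- adj[!adj$patient_id %in% biologic_before, ]
  note("no biologic before first resection", adj$patient_id)

  mab_added <- mab |>
    dplyr::inner_join(adj[c("patient_id", "adjuvant_start")], by = "patient_id") |>
    dplyr::filter(.data$date >= .data$adjuvant_start,
                  .data$date <= .data$adjuvant_start + config$adjuvant_window_days) |>
    dplyr::pull("patient_id") |> unique()
  adj <- adj[!adj$patient_id %in% mab_added, ]
  note("no biologic added within 3 months of chemotherapy start", adj$patient_id)

  off <- non_guideline_drug_patients(bundle, vocab)
  adj <- adj[!adj$patient_id %in% off, ]
  note("no non-guideline antitumor drug", adj$patient_id)

  # switch to second-line therapy within 6 months of the last adjuvant
  # dose's expected final dose date (adjuvant line derived with line rules)
  data_end <- setNames(bundle$patients$data_end, bundle$patients$patient_id)
  rx_split <- split(bundle$prescriptions, bundle$prescriptions$patient_id)
  switched <- vapply(seq_len(nrow(adj)), function(i) {
    pid <- adj$patient_id[i]
    lines <- derive_lines(rx_split[[pid]], anchor_date = adj$adjuvant_start[i],
                          data_end = data_end[[pid]], first_line_number = 0L,
                          patient_id = pid, vocab = vocab)
    nrow(lines) >= 2 &&
      days_between(lines$expected_final_dose_date[1], lines$start_date[2]) <=
        config$switch_window_days
  }, logical(1))
  adj <- adj[switched, ]
  note("switched to second-line within 6 months of last adjuvant dose", adj$patient_id)

  if (apply_enrollment) {
    adj <- adj[adj$adjuvant_start >= config$enrollment_start, ]
    note("adjuvant therapy started in or after enrollment start", adj$patient_id)
  }

  members <- tibble::tibble(
    patient_id = adj$patient_id, population = "early_recurrence",
    anchor_date = adj$surgery_date, therapy_start_date = adj$adjuvant_start,
    index_date = as.Date(NA),
    presumed_ras = presume_ras_status(bundle, adj$patient_id, config$analysis_window),
    in_folfiri_aa_subpop = FALSE, second_line_aa_drug = NA_character_,
    multi_aa = FALSE
  )
  list(members = members, log = log)
}

#' Select the early-recurrence population
#'
#' Patients presumed to have relapsed after curative-intent treatment: a
#' colorectal resection after the first confirmed CRC diagnosis, adjuvant
#' therapy (capecitabine, 5-FU, S-1, UFT or oxaliplatin) started within 3
#' months of surgery, and a switch to second-line therapy within 6 months of
#' the last adjuvant dose's expected final dose date. Patients with any
#' biologic before resection, a biologic added within 3 months of
#' chemotherapy start, or any non-guideline antitumor drug are excluded.
#'
#' @param bundle a `claims_bundle`.
#' @param config a [cohort_config()].
#' @param vocab vocabulary table.
#' @return list with `members` (cohort tibble) and `log` (criterion-by-
#'   criterion attrition, a `SelectionLog`).
#' @export
select_early_recurrence_population <- function(bundle, config = cohort_config(),
                                               vocab = drug_vocabulary()) {
  early_recurrence_candidates(bundle, config, vocab, apply_enrollment = TRUE)
}

#' Select the first-line population
#'
#' Patients presumed to start systemic therapy for advanced disease: first
#' prescription of bevacizumab, cetuximab or panitumumab after the first
#' confirmed CRC diagnosis anchors first-line therapy. Exclusions: age < 20
#' at the anchor, any of the three antibodies in the 365 days before the
#' anchor (washout), eligibility for the early-recurrence population, any
#' non-guideline antitumor drug, or an anchor before the enrollment start.
#'
#' @inheritParams select_early_recurrence_population
#' @return list with `members` and `log`.
#' @export
select_first_line_population <- function(bundle, config = cohort_config(),
                                         vocab = drug_vocabulary()) {
  log <- new_selection_log("patients in bundle", nrow(bundle$patients))
  note <- function(lab, ids) log <<- dplyr::bind_rows(log, new_selection_log(lab, length(ids)))

  dx <- first_crc_dx_by_patient(bundle, config)
  note("confirmed CRC (C18-C20) diagnosis in window", dx$patient_id)

  rx <- bundle$prescriptions
  mab <- rx[rx$drug_id %in% FIRST_LINE_MABS, c("patient_id", "date")]
  anchor <- mab |>
    dplyr::inner_join(dx, by = "patient_id") |>
    dplyr::filter(.data$date >= .data$dx_date,
                  .data$date >= config$diagnosis_window[1],
                  .data$date <= config$diagnosis_window[2]) |>
    dplyr::summarise(anchor_date = min_date(.data$date), .by = "patient_id")
  note("first-line monoclonal antibody after diagnosis", anchor$patient_id)

  pat <- bundle$patients[match(anchor$patient_id, bundle$patients$patient_id), ]
  anchor <- anchor[age_at(pat$birth_year, anchor$anchor_date) >= 20L, ]
  note("age >= 20 at first antibody prescription", anchor$patient_id)

  washed <- mab |>
    dplyr::inner_join(anchor, by = "patient_id") |>
    dplyr::filter(.data$date >= .data$anchor_date - config$washout_days,
                  .data$date <= .data$anchor_date - 1L) |>
    dplyr::pull("patient_id") |> unique()
  anchor <- anchor[!anchor$patient_id %in% washed, ]
  note("no prior antibody within 1-year washout", anchor$patient_id)

  er <- early_recurrence_candidates(bundle, config, vocab, apply_enrollment = FALSE)
  anchor <- anchor[!anchor$patient_id %in% er$members$patient_id, ]
  note("not eligible for the early-recurrence population", anchor$patient_id)

  off <- non_guideline_drug_patients(bundle, vocab)
  anchor <- anchor[!anchor$patient_id %in% off, ]
  note("no non-guideline antitumor drug", anchor$patient_id)

  anchor <- anchor[anchor$anchor_date >= config$enrollment_start, ]
  note("first-line therapy started in or after enrollment start", anchor$patient_id)

  members <- tibble::tibble(
    patient_id = anchor$patient_id, population = "first_line",
    anchor_date = anchor$anchor_date, therapy_start_date = anchor$anchor_date,
    index_date = as.Date(NA),
    presumed_ras = presume_ras_status(bundle, anchor$patient_id, config$analysis_window),
    in_folfiri_aa_subpop = FALSE, second_line_aa_drug = NA_character_,
    multi_aa = FALSE
  )
  list(members = members, log = log)
}

#' Select both analysis populations
#'
#' Convenience wrapper running [select_first_line_population()] and
#' [select_early_recurrence_population()]; the first-line exclusion rule
#' guarantees the two populations are disjoint.
#'
#' @inheritParams select_early_recurrence_population
#' @return list with `members` (stacked tibble) and `logs` (named list of
#'   selection logs).
#' @export
select_cohorts <- function(bundle, config = cohort_config(), vocab = drug_vocabulary()) {
  fl <- select_first_line_population(bundle, config, vocab)
  er <- select_early_recurrence_population(bundle, config, vocab)
  list(members = dplyr::bind_rows(fl$members, er$members),
       logs = list(first_line = fl$log, early_recurrence = er$log))
}

#' Fill index dates from derived lines
#'
#' The index date is the date of the first prescription for second-line
#' therapy, if present — available only after line derivation, so cohort
#' members carry `index_date = NA` until this step.
#'
#' @param members cohort tibble.
#' @param lines derived lines from [derive_lines_bundle()].
#' @return members with `index_date` filled where a second line exists.
#' @export
assign_index_dates <- function(members, lines) {
  second <- lines[lines$line_number == 2L, c("patient_id", "start_date")]
  idx <- match(members$patient_id, second$patient_id)
  members$index_date <- second$start_date[idx]
  members
}

#' Flag the second-line FOLFIRI plus antiangiogenic subpopulation
#'
#' A member enters the subpopulation when the initial 28-day regimen of
#' their second line has exactly the FOLFIRI backbone (5-FU + leucovorin +
#' irinotecan) plus at least one antiangiogenic drug. `second_line_aa_drug`
#' is the earliest-prescribed antiangiogenic in that window, ties broken by
#' the fixed order bevacizumab < ramucirumab < aflibercept beta; patients
#' with more than one antiangiogenic in the window are flagged `multi_aa`.
#'
#' @param members cohort tibble.
#' @param lines derived lines.
#' @param bundle the `claims_bundle` (for prescription dates in the window).
#' @param vocab vocabulary table.
#' @return members with `in_folfiri_aa_subpop`, `second_line_aa_drug` and
#'   `multi_aa` filled.
#' @export
select_folfiri_aa_subpopulation <- function(members, lines, bundle,
                                            vocab = drug_vocabulary()) {
  rx <- bundle$prescriptions[bundle$prescriptions$drug_id %in% ANTIANGIOGENIC_DRUGS, ]
  aa_rank <- setNames(seq_along(ANTIANGIOGENIC_DRUGS), ANTIANGIOGENIC_DRUGS)
  second <- lines[lines$line_number == 2L, ]
  folfiri_key <- sort(c("fluorouracil", "leucovorin", "irinotecan"))

  members$in_folfiri_aa_subpop <- FALSE
  members$second_line_aa_drug <- NA_character_
  members$multi_aa <- FALSE
  for (i in seq_len(nrow(members))) {
    row <- second[second$patient_id == members$patient_id[i], ]
    if (nrow(row) == 0) next
    base <- row$base_drugs[[1]]
    entries <- classify_drug(base, vocab)
    backbone_set <- sort(base[!entries$is_biologic])
    aa_in_base <- intersect(base, ANTIANGIOGENIC_DRUGS)
    if (!identical(backbone_set, folfiri_key) || length(aa_in_base) == 0) next
    win <- rx[rx$patient_id == members$patient_id[i] &
                rx$date >= row$start_date & rx$date <= row$start_date + 27L, ]
    win <- win[order(win$date, aa_rank[win$drug_id]), ]
    members$in_folfiri_aa_subpop[i] <- TRUE
    members$second_line_aa_drug[i] <- win$drug_id[1]
    members$multi_aa[i] <- length(unique(win$drug_id)) > 1
  }
  members
}
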