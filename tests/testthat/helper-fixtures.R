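# Fixture builders: small claims bundles constructed in code, anchored on a
# fixed origin so day offsets read like the rule windows they exercise.

D0 <- as.Date("2017-01-02")
day <- function(n) D0 + n

fx_patients <- function(ids, data_end = day(2000), birth_year = 1955L,
                        sex = "male", hospital_id = "H1") {
  tibble::tibble(patient_id = ids, sex = sex, birth_year = birth_year,
                 hospital_id = hospital_id, data_end = data_end)
}

fx_hospitals <- function() {
  tibble::tibble(hospital_id = "H1", bed_class = "200-499",
                 designated_cancer = TRUE)
}

fx_dx <- function(pid, dates, icd10 = "C18.7", confirmed = TRUE) {
  tibble::tibble(patient_id = pid, date = dates, icd10 = icd10,
                 confirmed = confirmed)
}

fx_rx <- function(pid, dates, drug_id, dose = NA_real_, route = "intravenous",
                  days_supplied = NA_integer_) {
  tibble::tibble(patient_id = pid, date = dates, drug_id = drug_id,
                 dose = dose, route = route, days_supplied = days_supplied)
}

# one prescription row per drug per date: rx_block(pid, 0:6 * 14, FOLFOX_BEV)
rx_block <- function(pid, offsets, drugs, dose = NA_real_) {
  tidyr::expand_grid(date = day(offsets), drug_id = drugs) |>
    dplyr::mutate(patient_id = pid, dose = dose, route = "intravenous",
                  days_supplied = NA_integer_) |>
    dplyr::select(patient_id, date, drug_id, dose, route, days_supplied)
}

FOLFOX <- c("fluorouracil", "leucovorin", "oxaliplatin")
FOLFIRI <- c("fluorouracil", "leucovorin", "irinotecan")

fx_bundle <- function(patients, diagnoses = NULL, prescriptions = NULL,
                      procedures = NULL, assessments = NULL,
                      hospitals = fx_hospitals(), validate = TRUE) {
  claims_bundle(patients, hospitals, diagnoses, prescriptions, procedures,
                assessments, validate = validate)
}

# default diagnosis making a patient CRC-eligible well before day 0
fx_eligible_dx <- function(pid) fx_dx(pid, day(-60))

# Brute-force product-limit oracle: walk the risk sets directly.
km_oracle <- function(duration, event) {
  times <- sort(unique(duration[event]))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    t <- times[i]
    n_risk <- sum(duration >= t)
    d <- sum(duration == t & event)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  tibble::tibble(time = times, estimate = surv)
}

expect_no_mismatch <- function(a, b) {
  expect_true(isTRUE(all.equal(as.data.frame(a), as.data.frame(b),
                               check.attributes = FALSE)))
}

# A clean first-line-population candidate: CRC diagnosis Dec 2016,
# bevacizumab-anchored FOLFOX from 2017-03-01.
first_line_fixture <- function(extra_rx = NULL, birth_year = 1962L) {
  rx <- dplyr::bind_rows(
    rx_block("P1", 0, c(FOLFOX, "bevacizumab")) |>
      dplyr::mutate(date = as.Date("2017-03-01") + (date - day(0))),
    extra_rx)
  fx_bundle(fx_patients("P1", birth_year = birth_year,
                        data_end = as.Date("2019-09-30")),
            diagnoses = fx_dx("P1", as.Date("2016-12-01")),
            prescriptions = rx)
}

# An early-recurrence candidate: surgery 2017-02-01, adjuvant capecitabine
# over 120 days (last dose covered to surgery + adjuvant_offset + 141),
# switch to FOLFIRI + bevacizumab at surgery + switch_offset.
er_fixture <- function(adjuvant_offset = 30, switch_offset = 240,
                       extra_rx = NULL) {
  s <- as.Date("2017-02-01")
  rx <- dplyr::bind_rows(
    rx_block("P1", seq(0, 120, 30), "capecitabine") |>
      dplyr::mutate(date = s + adjuvant_offset + (date - day(0))),
    rx_block("P1", 0, c(FOLFIRI, "bevacizumab")) |>
      dplyr::mutate(date = s + switch_offset + (date - day(0))),
    extra_rx)
  fx_bundle(fx_patients("P1", data_end = as.Date("2019-09-30")),
            diagnoses = fx_dx("P1", s - 20),
            prescriptions = rx,
            procedures = tibble::tibble(patient_id = "P1", date = s,
                                        kind = "colorectal_resection"))
}

# canonical comparable form of a lines table (list-columns flattened)
lines_key <- function(x) {
  x |>
    dplyr::arrange(patient_id, start_date) |>
    dplyr::mutate(
      base = purrr::map_chr(base_drugs, paste, collapse = ";"),
      all = purrr::map_chr(all_drugs, paste, collapse = ";"),
      adds = purrr::map_chr(additions, function(a) {
        paste(a$drug_id, a$date, sep = ":", collapse = ";")
      })) |>
    dplyr::select(patient_id, line_number, start_date, end_date, end_reason,
                  base, all, adds, expected_final_dose_date, completed,
                  evaluable_for_transition, transitioned)
}
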