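#' Expected final dose date of a prescription
#'
#' The date through which a prescription is expected to cover treatment:
#' `date + days_supplied` when a supply is recorded, otherwise `date +
#' default_cycle_days` from the drug vocabulary. This is the censoring point
#' when follow-up data ends before treatment visibly stops, and the clock
#' the 180-day discontinuation gap runs from.
#'
#' @param prescriptions a tibble with `date`, `drug_id` and optionally
#'   `days_supplied`; antitumor drugs only.
#' @param vocab vocabulary table.
#' @return a `Date` vector, one element per prescription row.
#' @export
#' @examples
#' expected_final_dose_date(
#'   tibble::tibble(date = as.Date("2017-04-10"), drug_id = "bevacizumab")
#' )
expected_final_dose_date <- function(prescriptions, vocab = drug_vocabulary()) {
  entries <- classify_drug(prescriptions$drug_id, vocab)
  if (!all(entries$is_antitumor)) {
    abort(paste0("expected_final_dose_date is defined for antitumor drugs; got: ",
                 paste(unique(prescriptions$drug_id[!entries$is_antitumor]), collapse = ", ")))
  }
  supplied <- if ("days_supplied" %in% names(prescriptions)) {
    prescriptions$days_supplied
  } else {
    rep(NA_integer_, nrow(prescriptions))
  }
  cover <- ifelse(is.na(supplied), entries$default_cycle_days, supplied)
  prescriptions$date + as.integer(cover)
}

#' Assemble a regimen from the initial 28-day window
#'
#' A line's regimen is the combination of all antitumor drugs (plus
#' leucovorin) prescribed within the initial 28-day period of the line's
#' first prescription, i.e. days `[anchor, anchor + 27]`.
#'
#' @param prescriptions tibble with `date`, `drug_id` for one patient.
#' @param anchor_date the line's first antitumor prescription date.
#' @param vocab vocabulary table.
#' @return one-row regimen tibble as from [name_regimen()].
#' @export
assemble_regimen <- function(prescriptions, anchor_date, vocab = drug_vocabulary()) {
  entries <- classify_drug(prescriptions$drug_id, vocab)
  keep <- (entries$is_antitumor | entries$drug_class == "leucovorin") &
    prescriptions$date >= anchor_date &
    prescriptions$date <= anchor_date + 27L
  drugs <- unique(prescriptions$drug_id[keep])
  if (length(drugs) == 0) abort("no antitumor prescriptions in the 28-day window")
  name_regimen(drugs, vocab)
}

# Internal single-patient segmentation. `prescriptions` must already be
# restricted to antitumor drugs + leucovorin at/after the anchor and sorted.
segment_lines <- function(prescriptions, anchor_date, first_line_number,
                          data_end, vocab) {
  if (nrow(prescriptions) == 0) return(empty_lines_table())

  is_antitumor <- setNames(vocab$is_antitumor, vocab$drug_id)
  is_biologic <- setNames(vocab$is_biologic, vocab$drug_id)
  cycle_days <- setNames(vocab$default_cycle_days, vocab$drug_id)

  rx <- prescriptions
  supplied <- if ("days_supplied" %in% names(rx)) rx$days_supplied else rep(NA_integer_, nrow(rx))
  rx_efd <- rx$date + as.integer(ifelse(is.na(supplied),
                                        cycle_days[rx$drug_id], supplied))
  # group prescriptions by date: same-day claims are one decision point
  dates <- sort(unique(rx$date))

  lines <- list()
  close_line <- function(state, end_date, end_reason) {
    all_drugs <- union(state$base, state$additions$drug_id)
    reg <- name_regimen(all_drugs, vocab)
    base_reg <- name_regimen(state$base, vocab)
    lines[[length(lines) + 1]] <<- tibble::tibble(
      line_number = state$number,
      start_date = state$start,
      end_date = end_date,
      end_reason = end_reason,
      base_drugs = list(sort(state$base)),
      additions = list(state$additions),
      all_drugs = list(sort(all_drugs)),
      backbone = base_reg$backbone,
      base_label = base_reg$label,
      regimen_label = reg$label,
      multi_biologic = reg$multi_biologic,
      expected_final_dose_date = state$efd,
      n_prescriptions = state$n_rx
    )
  }
  new_state <- function(number, start) {
    list(number = number, start = start, base = character(),
         additions = tibble::tibble(drug_id = character(), date = as.Date(character())),
         efd = as.Date(NA), n_rx = 0L)
  }
  next_number <- function(num) if (num == 0L) 2L else num + 1L

  state <- new_state(first_line_number, dates[1])
  for (d in seq_along(dates)) {
    day <- dates[d]
    idx <- which(rx$date == day)
    drugs <- unique(rx$drug_id[idx])
    antitumor <- drugs[is_antitumor[drugs]]
    day_efd <- suppressWarnings(max(rx_efd[idx][is_antitumor[rx$drug_id[idx]]]))

    absorb <- function(state) {
      state$n_rx <- state$n_rx + length(idx)
      if (length(antitumor) > 0) {
        state$efd <- max(state$efd, day_efd, na.rm = TRUE)
      }
      state
    }

    if (day <= state$start + 27L) {
      # regimen-assembly window: everything prescribed here joins the base
      state$base <- union(state$base, drugs)
      state <- absorb(state)
      next
    }

    # rule 1: discontinuation of all antitumor drugs for >= 180 days,
    # measured from the running expected-final-dose date of the line
    if (days_between(state$efd, day) >= 180L) {
      close_line(state, end_date = state$efd, end_reason = "gap_180")
      state <- new_state(next_number(state$number), day)
      state$base <- drugs
      state <- absorb(state)
      next
    }

    current <- union(state$base, state$additions$drug_id)
    new_drugs <- setdiff(antitumor, current)
    if (length(new_drugs) > 0) {
      # biologic-addition exception: only for second and later lines, only
      # when the running regimen is chemotherapy-only, and only when the
      # prescription introduces nothing but biologics
      exception <- state$number >= 2L &&
        all(is_biologic[new_drugs]) &&
        !any(is_biologic[current])
      if (exception) {
        state$additions <- dplyr::bind_rows(
          state$additions, tibble::tibble(drug_id = new_drugs, date = day))
        state <- absorb(state)
      } else {
        # rule 2: prescription of antitumor drugs not in the regimen
        close_line(state, end_date = day, end_reason = "new_drug")
        state <- new_state(next_number(state$number), day)
        state$base <- drugs
        state <- absorb(state)
      }
      next
    }

    # in-regimen prescription: extends exposure, nothing else
    state <- absorb(state)
  }
  close_line(state, end_date = min(state$efd, data_end), end_reason = "data_end")
  dplyr::bind_rows(lines)
}

empty_lines_table <- function() {
  tibble::tibble(
    patient_id = character(), line_number = integer(),
    start_date = as.Date(character()), end_date = as.Date(character()),
    end_reason = character(), base_drugs = list(), additions = list(),
    all_drugs = list(), backbone = character(), base_label = character(),
    regimen_label = character(), multi_biologic = logical(),
    expected_final_dose_date = as.Date(character()), n_prescriptions = integer(),
    duration_days = integer(), completed = logical(),
    evaluable_for_transition = logical(), transitioned = logical()
  )
}

#' Derive therapy lines for one patient
#'
#' Segments a patient's antitumor prescriptions into lines of therapy.
#' The first line is anchored at `anchor_date` (the first qualifying
#' monoclonal-antibody prescription for the first-line population; the first
#' adjuvant prescription for the early-recurrence population) and its
#' regimen is the drug combination of the initial 28-day window. A line ends
#' at whichever fires first of
#' 1. the 180-day gap rule: the next antitumor prescription comes 180 days
#'    or more after the line's running expected-final-dose date
#'    (`end_reason = "gap_180"`, the line ends at that expected-final-dose
#'    date), or
#' 2. the new-drug rule: a prescription contains an antitumor drug outside
#'    the current regimen (`end_reason = "new_drug"`, the line ends at — and
#'    the next line starts at — that prescription's date),
#'
#' except that for second and later lines a biologic prescribed into a
#' chemotherapy-only regimen is recorded as a regimen addition, not a line
#' end. The last line ends at `min(expected final dose, data_end)` with
#' `end_reason = "data_end"` when neither rule fires.
#'
#' @param prescriptions tibble of one patient's prescriptions (`date`,
#'   `drug_id`, optional `days_supplied`); non-antitumor drugs other than
#'   leucovorin and prescriptions before the anchor are ignored.
#' @param anchor_date first-line anchor date; must carry a prescription.
#' @param data_end the patient's data-availability horizon.
#' @param first_line_number `1L` for the first-line population or `0L` for
#'   an adjuvant first line; subsequent lines are numbered 2, 3, ... in both
#'   cases (line 0 is displayed as "adjuvant").
#' @param patient_id optional id stamped on the output.
#' @param vocab vocabulary table.
#' @return a tibble of therapy lines with regimen list-columns, end reasons,
#'   durations (`end - start` in days, half-open interval) and the 60-day
#'   completion/evaluability flags.
#' @export
derive_lines <- function(prescriptions, anchor_date, data_end,
                         first_line_number = 1L, patient_id = NA_character_,
                         vocab = drug_vocabulary()) {
  if (nrow(prescriptions) == 0) return(empty_lines_table())
  entries <- classify_drug(prescriptions$drug_id, vocab)
  keep <- (entries$is_antitumor | entries$drug_class == "leucovorin") &
    prescriptions$date >= anchor_date
  rx <- dplyr::arrange(prescriptions[keep, , drop = FALSE], .data$date)
  if (nrow(rx) == 0) return(empty_lines_table())
  if (min(rx$date) != anchor_date) {
    abort("anchor_date must carry the line's first antitumor prescription")
  }
  lines <- segment_lines(rx, anchor_date, first_line_number, data_end, vocab)
  n <- nrow(lines)
  following <- seq_len(n) < n
  status <- completion_status(lines, following, data_end)
  lines$duration_days <- days_between(lines$start_date, lines$end_date)
  lines$completed <- status$completed
  lines$evaluable_for_transition <- status$evaluable_for_transition
  lines$transitioned <- following
  lines <- dplyr::mutate(lines, patient_id = patient_id, .before = 1)
  lines
}

#' Completion and transition-evaluability status of derived lines
#'
#' A line is *evaluable for transition* when a subsequent line exists or
#' more than 60 days of data remain after its end date, so that
#' non-transition is observable. Treatment is *completed* when the interval
#' from the expected final dose date to the data horizon is 60 days or
#' greater; otherwise the treatment duration is censored at the expected
#' final dose date.
#'
#' @param lines derived-lines tibble (needs `end_date` and
#'   `expected_final_dose_date`).
#' @param following_line_exists logical vector, one element per line.
#' @param data_end the patient's data horizon.
#' @return tibble with `completed` and `evaluable_for_transition`.
#' @export
completion_status <- function(lines, following_line_exists, data_end) {
  tibble::tibble(
    completed = days_between(lines$expected_final_dose_date, data_end) >= 60L,
    evaluable_for_transition = following_line_exists |
      days_between(lines$end_date, data_end) > 60L
  )
}

line_label <- function(line_number) {
  ifelse(line_number == 0L, "adjuvant", as.character(line_number))
}

#' Derive therapy lines for every cohort member in a bundle
#'
#' Applies [derive_lines()] per member, anchoring at the member's
#' `therapy_start_date` with an adjuvant first line for the early-recurrence
#' population.
#'
#' @param bundle a `claims_bundle`.
#' @param members cohort tibble from the selection functions.
#' @param vocab vocabulary table.
#' @return stacked lines tibble with a `line_label` column.
#' @export
derive_lines_bundle <- function(bundle, members, vocab = drug_vocabulary()) {
  data_end <- setNames(bundle$patients$data_end, bundle$patients$patient_id)
  rx_by_patient <- split(bundle$prescriptions, bundle$prescriptions$patient_id)
  out <- purrr::pmap(
    list(members$patient_id, members$therapy_start_date, members$population),
    function(pid, start, population) {
      rx <- rx_by_patient[[pid]]
      if (is.null(rx)) return(empty_lines_table())
      derive_lines(rx, anchor_date = start, data_end = data_end[[pid]],
                   first_line_number = if (population == "early_recurrence") 0L else 1L,
                   patient_id = pid, vocab = vocab)
    })
  lines <- dplyr::bind_rows(out)
  dplyr::mutate(lines, line_label = line_label(.data$line_number),
                .after = "line_number")
}
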