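# Single-patient claims emission. The generator works from a latent
# timeline (lines with known starts, regimens, durations and end reasons)
# and writes only claims; the line structure is recovered downstream by
# derive_lines(), which is exactly what the noise-free equivalence
# invariant tests.
simulate_patient <- function(pid, hospitals, config, vocab = drug_vocabulary()) {
  cycle <- setNames(vocab$default_cycle_days, vocab$drug_id)
  is_bio <- setNames(vocab$is_biologic, vocab$drug_id)
  is_at <- setNames(vocab$is_antitumor, vocab$drug_id)
  class_of <- setNames(vocab$drug_class, vocab$drug_id)
  prev <- config$covariate_prevalence
  menus <- config$regimen_menu
  analysis_end <- cohort_config()$analysis_window[2]

  line_efd <- function(rx) {
    at <- rx[is_at[rx$drug_id], , drop = FALSE]
    max(at$date + as.integer(cycle[at$drug_id]))
  }

  # ---- demographics and disease presentation ---------------------------
  er <- stats::runif(1) < config$p_early_recurrence
  wild_intent <- stats::runif(1) < config$p_ras_wildtype
  hosp_i <- sample.int(nrow(hospitals), 1)
  male <- stats::runif(1) < prev[["male"]]
  left <- stats::runif(1) < prev[["left_sided"]]
  right <- stats::runif(1) < 0.34
  bmi <- round(min(45, max(13, stats::rnorm(1, 22.3, 3.7))), 1)
  adl_total <- if (stats::runif(1) < prev[["adl_not_independent"]]) {
    sample(seq(40L, 95L, 5L), 1)
  } else 100L
  bmi_missing <- stats::runif(1) < config$missing_bmi
  adl_missing <- stats::runif(1) < config$missing_adl

  ew <- config$enrollment_window
  start1 <- ew[1] + sample.int(days_between(ew[1], ew[2]) + 1L, 1) - 1L
  age1 <- round(min(90, max(25, stats::rnorm(1, 66, 10))))
  birth_year <- as.integer(format(start1, "%Y")) - as.integer(age1) -
    as.integer(format(start1, "%m-%d") < "07-01")

  if (er) {
    surgery <- start1 - sample(14:60, 1)
    dx_date <- surgery - sample(7:30, 1)
    base1 <- sample_menu(menus$adjuvant)
    d1 <- sample(84:183, 1)
    first_num <- 0L
  } else {
    surgery <- as.Date(NA)
    dx_date <- start1 - sample(14:120, 1)
    base1 <- sample_menu(if (wild_intent) menus$first_line_wild else menus$first_line_mutant)
    d1 <- as.integer(min(600, max(28, round(stats::rlnorm(1, log(160), 0.5)))))
    first_num <- 1L
  }

  # ---- prescription emission for one line ------------------------------
  emit_line <- function(start, duration, base, addition_drug = NULL,
                        addition_date = NULL, aa_single_use = NA,
                        aa_dose_reduced = FALSE) {
    rows <- purrr::map(base, function(d) {
      if (d %in% ANTIANGIOGENIC_DRUGS && !is.na(aa_single_use)) {
        dates <- if (aa_single_use) start else aa_schedule(start, duration, config)
        if (!aa_single_use && length(dates) == 1) {
          # a multi-use outcome always realizes its second biweekly dose,
          # even on the shortest (28-day) lines
          dates <- c(dates, start + 14L)
        }
        dose <- rep(AA_DOSE[[d]], length(dates))
        if (aa_dose_reduced && length(dose) >= 2) {
          dose[-1] <- dose[-1] * 0.8
        }
      } else {
        dates <- drug_schedule(start, duration, as.integer(cycle[[d]]),
                               config$cycle_jitter_days)
        dose <- if (d %in% ANTIANGIOGENIC_DRUGS) {
          rep(AA_DOSE[[d]], length(dates))
        } else rep(NA_real_, length(dates))
      }
      tibble::tibble(patient_id = pid, date = dates, drug_id = d, dose = dose,
                     route = if (d %in% ORAL_DRUGS) "oral" else "intravenous",
                     days_supplied = NA_integer_)
    })
    if (!is.null(addition_drug)) {
      rel <- days_between(addition_date, start + duration)
      dates <- drug_schedule(addition_date, rel, as.integer(cycle[[addition_drug]]),
                             config$cycle_jitter_days)
      rows <- c(rows, list(tibble::tibble(
        patient_id = pid, date = dates, drug_id = addition_drug,
        dose = if (addition_drug %in% ANTIANGIOGENIC_DRUGS)
          rep(AA_DOSE[[addition_drug]], length(dates)) else rep(NA_real_, length(dates)),
        route = "intravenous", days_supplied = NA_integer_)))
    }
    dplyr::arrange(dplyr::bind_rows(rows), .data$date)
  }

  # ---- line 1 / adjuvant -----------------------------------------------
  rx1 <- emit_line(start1, d1, base1)
  efd1 <- line_efd(rx1)

  p_trans <- config$line_transition_probs
  target_lines <- 1L
  for (j in seq_along(p_trans)) {
    reach <- if (er && j == 1) TRUE else stats::runif(1) < p_trans[j]
    if (!reach) break
    target_lines <- target_lines + 1L
  }

  specs <- list(list(number = first_num, start = start1, base = base1,
                     addition_drug = NULL, addition_date = as.Date(NA),
                     rx = rx1, efd = efd1, duration = d1,
                     end = as.Date(NA), reason = NA_character_))

  x <- NULL; single_use <- NA; start2 <- as.Date(NA); duration2 <- NA_integer_
  conc <- list(qual = FALSE, quant = FALSE, antihyp = FALSE,
               antichol = FALSE, anticoag = FALSE)
  in_subpop <- FALSE; subpop_drug <- NA_character_
  base2 <- character(); addition2 <- NULL

  if (target_lines >= 2) {
    base2_full <- sample_menu(if (wild_intent) menus$second_line_wild else menus$second_line_mutant)

    # delayed-biologic addition intent for line 2: only when the remaining
    # chemotherapy backbone still introduces a new drug against line 1, so
    # the line boundary stays a new-drug boundary (the biologic, arriving
    # after the 28-day window into a chemotherapy-only regimen, is then an
    # addition under the exception, never a line trigger)
    bio2 <- base2_full[is_bio[base2_full]]
    add2_intent <- length(bio2) == 1 &&
      stats::runif(1) < config$p_biologic_addition &&
      length(setdiff(setdiff(base2_full, bio2)[is_at[setdiff(base2_full, bio2)]],
                     base1)) > 0
    base2_day0 <- if (add2_intent) setdiff(base2_full, bio2) else base2_full

    new_drugs <- setdiff(base2_day0[is_at[base2_day0]], base1)
    if (length(new_drugs) > 0) {
      delta <- if (er) sample(14:150, 1) else sample(7:90, 1)
      start2 <- efd1 + delta
      specs[[1]]$end <- start2
      specs[[1]]$reason <- "new_drug"
    } else {
      start2 <- efd1 + 180L + sample(0:60, 1)
      specs[[1]]$end <- efd1
      specs[[1]]$reason <- "gap_180"
    }

    # presumed RAS status as the downstream rule will see it: any anti-EGFR
    # prescription dated inside the analysis window
    ras_wild_final <- any(base1 %in% ANTI_EGFR_DRUGS) ||
      (any(base2_full %in% ANTI_EGFR_DRUGS) && start2 <= analysis_end)

    x <- setNames(as.list(rep(FALSE, length(COVARIATE_TERMS))), COVARIATE_TERMS)
    x$designated_cancer_hospital <- hospitals$designated_cancer[hosp_i]
    x$age_ge70_at_2l <- age_at(birth_year, start2) >= 70L
    x$male <- male
    x$left_sided <- left
    x$presumed_ras_wild <- ras_wild_final
    x$bmi_le_18_5 <- bmi <= 18.5
    x$adl_not_independent <- adl_total < 100L
    x$oral_fp_prev_line <- any(class_of[base1] == "fluoropyrimidine_oral")
    x$irinotecan_prev_line <- "irinotecan" %in% base1
    x$prev_line_ge180d <- days_between(start1, specs[[1]]$end) >= 180L
    x$early_recurrence <- er

    single_use <- stats::runif(1) <
      plogis_linpred(tibble::as_tibble(x[LOGISTIC_TERMS]), config)

    aa_in_base <- intersect(base2_day0, ANTIANGIOGENIC_DRUGS)
    p_single_ctx <- length(aa_in_base) > 0 && single_use
    conc$qual <- stats::runif(1) < prev[["qual_proteinuria_2l"]]
    conc$quant <- stats::runif(1) < if (p_single_ctx) 0.127 else 0.063
    conc$antihyp <- stats::runif(1) < if (p_single_ctx) 0.271 else 0.204
    conc$antichol <- stats::runif(1) < prev[["anticholinergic_2l"]]
    conc$anticoag <- stats::runif(1) < prev[["anticoagulant_2l"]]
    x$qual_proteinuria_2l <- conc$qual
    x$quant_proteinuria_2l <- conc$quant
    x$antihypertensive_2l <- conc$antihyp
    x$anticholinergic_2l <- conc$antichol
    x$anticoagulant_2l <- conc$anticoag

    rate <- config$baseline_hazard * exp(cox_linpred(tibble::as_tibble(x), config))
    t_overall <- max(28, round(stats::rexp(1, rate)))

    m <- target_lines - 1L
    d_post <- if (m == 1) t_overall else {
      w <- diff(sort(c(0, stats::runif(m - 1), 1)))
      pmax(28L, as.integer(round(t_overall * w)))
    }

    for (j in 2:target_lines) {
      dj <- as.integer(d_post[j - 1])
      if (j == 2) {
        # boundary and addition intent already decided above; cancel the
        # addition when the line is too short to host it
        add_drug <- if (add2_intent && dj >= 70) bio2 else NULL
        base_j <- if (is.null(add_drug)) base2_full else base2_day0
        start_j <- start2
      } else {
        base_full_j <- sample_menu(menus$later_line)
        prev_spec <- specs[[length(specs)]]
        prev_all <- c(prev_spec$base, prev_spec$addition_drug)

        bio_j <- base_full_j[is_bio[base_full_j]]
        chemo_j <- setdiff(base_full_j, bio_j)
        add_drug <- if (length(bio_j) == 1 && dj >= 70 &&
                          stats::runif(1) < config$p_biologic_addition &&
                          length(setdiff(chemo_j[is_at[chemo_j]], prev_all)) > 0) {
          bio_j
        } else NULL
        base_j <- if (is.null(add_drug)) base_full_j else chemo_j

        # a day-0 set triggers a new line only when it introduces a drug the
        # previous regimen would not absorb: for previous lines >= 2,
        # biologics entering a chemotherapy-only regimen are absorbed as
        # additions, so such sets transition via the 180-day gap instead
        new_at <- setdiff(base_j[is_at[base_j]], prev_all)
        absorbed_bio <- prev_spec$number >= 2L && length(new_at) > 0 &&
          all(is_bio[new_at]) && !any(is_bio[prev_all])
        if (length(new_at) > 0 && !absorbed_bio) {
          start_j <- prev_spec$efd + sample(7:90, 1)
          specs[[length(specs)]]$end <- start_j
          specs[[length(specs)]]$reason <- "new_drug"
        } else {
          start_j <- prev_spec$efd + 180L + sample(0:60, 1)
          specs[[length(specs)]]$end <- prev_spec$efd
          specs[[length(specs)]]$reason <- "gap_180"
        }
      }
      add_date <- if (is.null(add_drug)) as.Date(NA) else start_j + 28L + sample(0:14, 1)

      aa_su <- NA
      aa_red <- FALSE
      if (j == 2) {
        base2 <- base_j
        addition2 <- add_drug
        aa_base_j <- intersect(base_j, ANTIANGIOGENIC_DRUGS)
        if (length(aa_base_j) > 0) {
          aa_su <- single_use
          aa_red <- stats::runif(1) < config$p_dose_reduction
          in_subpop <- identical(sort(base_j[!is_bio[base_j]]),
                                 sort(c("fluorouracil", "leucovorin", "irinotecan")))
          if (in_subpop) subpop_drug <- aa_base_j[1]
        }
        duration2 <- dj
      }

      rx_j <- emit_line(start_j, dj, base_j, add_drug, add_date, aa_su, aa_red)
      specs[[length(specs) + 1]] <- list(
        number = j, start = start_j, base = base_j, addition_drug = add_drug,
        addition_date = add_date, rx = rx_j, efd = line_efd(rx_j),
        duration = dj, end = as.Date(NA), reason = NA_character_)
    }
  } else {
    ras_wild_final <- any(base1 %in% ANTI_EGFR_DRUGS)
  }

  # ---- data horizon and truth line closure -----------------------------
  rx_all <- dplyr::bind_rows(purrr::map(specs, "rx"))
  lag <- sample(seq(config$data_end_lag_days[1], config$data_end_lag_days[2]), 1)
  data_end <- max(rx_all$date) + lag
  k <- length(specs)
  specs[[k]]$end <- min(specs[[k]]$efd, data_end)
  specs[[k]]$reason <- "data_end"

  truth_lines <- purrr::imap(specs, function(s, j) {
    all_drugs <- c(s$base, s$addition_drug)
    reg <- name_regimen(all_drugs, vocab)
    base_reg <- name_regimen(s$base, vocab)
    additions <- if (is.null(s$addition_drug)) {
      tibble::tibble(drug_id = character(), date = as.Date(character()))
    } else tibble::tibble(drug_id = s$addition_drug, date = s$addition_date)
    tibble::tibble(
      patient_id = pid, line_number = s$number, start_date = s$start,
      end_date = s$end, end_reason = s$reason,
      base_drugs = list(sort(s$base)), additions = list(additions),
      all_drugs = list(sort(all_drugs)), backbone = base_reg$backbone,
      base_label = base_reg$label, regimen_label = reg$label,
      expected_final_dose_date = s$efd,
      completed = days_between(s$efd, data_end) >= 60L,
      evaluable_for_transition = j < k | days_between(s$end, data_end) > 60L,
      transitioned = j < k)
  }) |> dplyr::bind_rows()

  # ---- realized second-line antiangiogenic bookkeeping -----------------
  n_aa_rx <- NA_integer_; gap_ge21 <- NA; dose_reduced <- NA
  if (target_lines >= 2 && length(intersect(base2, ANTIANGIOGENIC_DRUGS)) > 0) {
    rx2 <- specs[[2]]$rx
    aa2 <- rx2[rx2$drug_id %in% ANTIANGIOGENIC_DRUGS, ]
    n_aa_rx <- nrow(aa2)
    gap_ge21 <- n_aa_rx >= 2 && any(diff(as.numeric(aa2$date)) >= 21)
    dose_reduced <- n_aa_rx >= 2 && any(diff(aa2$dose) < 0)
  }

  # ---- claims tables ----------------------------------------------------
  codes <- c(if (left) sample(SIDED_LEFT_CODES, 1),
             if (right) sample(SIDED_RIGHT_CODES, 1))
  if (length(codes) == 0) codes <- "C18.9"
  dx_dates <- c(dx_date, purrr::map_vec(specs, "start"))
  diagnoses <- tidyr::expand_grid(date = dx_dates, icd10 = codes) |>
    dplyr::mutate(patient_id = pid, confirmed = TRUE, .before = 1)
  if (stats::runif(1) < 0.10) {
    diagnoses <- dplyr::bind_rows(diagnoses, tibble::tibble(
      patient_id = pid, date = dx_date, icd10 = "C18.9", confirmed = FALSE))
  }

  procedures <- tibble::tibble(patient_id = character(), date = as.Date(character()),
                               kind = character())
  if (er) {
    procedures <- dplyr::bind_rows(procedures, tibble::tibble(
      patient_id = pid, date = surgery, kind = "colorectal_resection"))
  }
  conc_rx <- tibble::tibble(patient_id = character(), date = as.Date(character()),
                            drug_id = character(), dose = numeric(),
                            route = character(), days_supplied = integer())
  if (target_lines >= 2) {
    second_dates <- start2
    if (!is.na(duration2) && duration2 > 40) second_dates <- c(start2, start2 + 30L)
    add_proc <- function(flag, kind) {
      if (flag) tibble::tibble(patient_id = pid, date = second_dates, kind = kind)
    }
    procedures <- dplyr::bind_rows(procedures,
                                   add_proc(conc$qual, "proteinuria_qualitative"),
                                   add_proc(conc$quant, "proteinuria_quantitative"))
    add_med <- function(flag, drug) {
      if (flag) tibble::tibble(patient_id = pid, date = second_dates, drug_id = drug,
                               dose = NA_real_, route = "oral",
                               days_supplied = NA_integer_)
    }
    conc_rx <- dplyr::bind_rows(conc_rx,
                                add_med(conc$antihyp, "amlodipine"),
                                add_med(conc$antichol, "butylscopolamine"),
                                add_med(conc$anticoag, "warfarin"))
  }

  assess <- list()
  line_starts <- purrr::map_vec(specs, "start")
  if (!bmi_missing) {
    assess <- c(assess, list(tibble::tibble(
      patient_id = pid, date = line_starts, kind = "bmi", value = bmi,
      items = NA_character_)))
  }
  if (!adl_missing) {
    assess <- c(assess, list(tibble::tibble(
      patient_id = pid, date = line_starts, kind = "barthel",
      value = as.numeric(adl_total), items = barthel_items_for_total(adl_total))))
  }
  assessments <- dplyr::bind_rows(assess)

  truth_patient <- tibble::tibble(
    patient_id = pid,
    population = if (er) "early_recurrence" else "first_line",
    presumed_ras = if (ras_wild_final) "wild_type" else "mutant",
    n_lines = k,
    index_date = start2,
    in_folfiri_aa_subpop = in_subpop,
    second_line_aa_drug = subpop_drug,
    # the outcome is the realized prescription count (a short line can end
    # after one antiangiogenic claim even when the mechanism drew multi-use)
    single_use = if (!is.na(n_aa_rx)) n_aa_rx == 1L else NA,
    n_aa_rx = n_aa_rx, gap_ge21 = gap_ge21, dose_reduced = dose_reduced,
    duration_days = if (target_lines >= 2) {
      days_between(start2, specs[[k]]$efd)
    } else NA_integer_,
    event = if (target_lines >= 2) days_between(specs[[k]]$efd, data_end) >= 60L else NA,
    data_end = data_end,
    bmi_value = bmi, adl_total = adl_total,
    bmi_missing = bmi_missing, adl_missing = adl_missing,
    right_sided = right
  )
  if (!is.null(x)) {
    truth_patient <- dplyr::bind_cols(truth_patient, tibble::as_tibble(x))
  } else {
    na_x <- setNames(as.list(rep(NA, length(COVARIATE_TERMS))), COVARIATE_TERMS)
    na_x$male <- male; na_x$left_sided <- left; na_x$early_recurrence <- er
    na_x$bmi_le_18_5 <- bmi <= 18.5; na_x$adl_not_independent <- adl_total < 100L
    na_x$presumed_ras_wild <- ras_wild_final
    truth_patient <- dplyr::bind_cols(truth_patient, tibble::as_tibble(na_x))
  }

  list(
    patient = tibble::tibble(patient_id = pid, sex = if (male) "male" else "female",
                             birth_year = birth_year, hospital_id = hospitals$hospital_id[hosp_i],
                             data_end = data_end),
    diagnoses = diagnoses[, c("patient_id", "date", "icd10", "confirmed")],
    prescriptions = dplyr::bind_rows(rx_all, conc_rx),
    procedures = procedures,
    assessments = assessments,
    truth_patient = truth_patient,
    truth_lines = truth_lines
  )
}
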