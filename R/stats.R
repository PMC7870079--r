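#' Build covariate vectors at second-line start
#'
#' Assembles the covariate set used by the logistic and Cox stages for each
#' cohort member with an index date (start of second-line therapy).
#' Baseline fields derive only from events in the one-year baseline window
#' `[index - 365, index]`: tumour sidedness from confirmed diagnosis codes
#' (right-sided C18.0-C18.4; left-sided C18.5-C18.7, C19, C20; both flags
#' may be true, neither for C18.8/C18.9 only), BMI and Barthel ADL from the
#' latest assessment in the window (ADL not independent = total below 100).
#' Previous-line treatment flags use that line's full regimen including
#' additions. Concomitant `_2l` flags derive only from events within the
#' second line's `[start, end)`.
#'
#' Missing BMI/ADL yield `NA` flags plus explicit `bmi_missing`/
#' `adl_missing` columns; the model stages are complete-case and report the
#' exclusion count, never imputing.
#'
#' @param bundle a `claims_bundle`.
#' @param members cohort members; every row must have an `index_date`.
#' @param lines derived lines.
#' @param vocab vocabulary table.
#' @return tibble with `patient_id`, the [COVARIATE_TERMS] columns and the
#'   missingness flags.
#' @export
build_covariates <- function(bundle, members, lines, vocab = drug_vocabulary()) {
  if (anyNA(members$index_date)) {
    abort("build_covariates requires an index_date for every member")
  }
  pat <- bundle$patients[match(members$patient_id, bundle$patients$patient_id), ]
  hosp <- bundle$hospitals[match(pat$hospital_id, bundle$hospitals$hospital_id), ]
  class_of <- setNames(vocab$drug_class, vocab$drug_id)
  conc_class <- c(antihypertensive = "antihypertensive_2l",
                  anticholinergic = "anticholinergic_2l",
                  anticoagulant = "anticoagulant_2l")

  dx <- bundle$diagnoses[bundle$diagnoses$confirmed, ]
  second <- lines[lines$line_number == 2L, ]
  prev_lines <- lines[lines$line_number < 2L, ]

  rows <- purrr::map(seq_len(nrow(members)), function(i) {
    pid <- members$patient_id[i]
    index <- members$index_date[i]
    lo <- index - 365L

    dxi <- dx[dx$patient_id == pid & dx$date >= lo & dx$date <= index, ]
    right <- any(grepl("^C18\\.[0-4]$", dxi$icd10))
    left <- any(grepl("^C18\\.[5-7]$", dxi$icd10) | grepl("^C(19|20)", dxi$icd10))

    ai <- bundle$assessments[bundle$assessments$patient_id == pid &
                               bundle$assessments$date >= lo &
                               bundle$assessments$date <= index, ]
    bmi_rows <- ai[ai$kind == "bmi", ]
    bmi <- if (nrow(bmi_rows) > 0) bmi_rows$value[which.max(bmi_rows$date)] else NA_real_
    adl_rows <- ai[ai$kind == "barthel", ]
    adl <- if (nrow(adl_rows) > 0) adl_rows$value[which.max(adl_rows$date)] else NA_real_

    prev <- prev_lines[prev_lines$patient_id == pid, ]
    prev <- prev[which.max(prev$line_number), ]
    prev_drugs <- if (nrow(prev) > 0) prev$all_drugs[[1]] else character()

    sec <- second[second$patient_id == pid, ]
    if (nrow(sec) == 1) {
      rx2 <- bundle$prescriptions[bundle$prescriptions$patient_id == pid &
                                    bundle$prescriptions$date >= sec$start_date &
                                    bundle$prescriptions$date < sec$end_date, ]
      classes2 <- class_of[rx2$drug_id]
      proc2 <- bundle$procedures[bundle$procedures$patient_id == pid &
                                   bundle$procedures$date >= sec$start_date &
                                   bundle$procedures$date < sec$end_date, ]
    } else {
      classes2 <- character()
      proc2 <- bundle$procedures[0, ]
    }

    tibble::tibble(
      patient_id = pid,
      designated_cancer_hospital = hosp$designated_cancer[i],
      age_ge70_at_2l = age_at(pat$birth_year[i], index) >= 70L,
      male = pat$sex[i] == "male",
      left_sided = left,
      right_sided = right,
      presumed_ras_wild = members$presumed_ras[i] == "wild_type",
      bmi_le_18_5 = if (is.na(bmi)) NA else bmi <= 18.5,
      adl_not_independent = if (is.na(adl)) NA else adl < 100,
      oral_fp_prev_line = any(class_of[prev_drugs] == "fluoropyrimidine_oral"),
      irinotecan_prev_line = "irinotecan" %in% prev_drugs,
      prev_line_ge180d = nrow(prev) > 0 &&
        days_between(prev$start_date, prev$end_date) >= 180L,
      early_recurrence = members$population[i] == "early_recurrence",
      qual_proteinuria_2l = any(proc2$kind == "proteinuria_qualitative"),
      quant_proteinuria_2l = any(proc2$kind == "proteinuria_quantitative"),
      antihypertensive_2l = any(classes2 == "antihypertensive", na.rm = TRUE),
      anticholinergic_2l = any(classes2 == "anticholinergic", na.rm = TRUE),
      anticoagulant_2l = any(classes2 == "anticoagulant", na.rm = TRUE),
      bmi_missing = is.na(bmi),
      adl_missing = is.na(adl))
  })
  dplyr::bind_rows(rows)
}

#' Kaplan-Meier duration estimate
#'
#' Product-limit estimation of a treatment-duration distribution. The
#' median is the first time at which the survival estimate falls to 0.5 or
#' below; its confidence interval and the pointwise curve intervals use the
#' log-log transform. The restricted mean (restricted to the largest
#' observed time) is reported with a flag when the largest observation is
#' censored, in which case the mean is underestimated.
#'
#' @param records tibble with `duration_days` (>= 0) and `event` (TRUE =
#'   completed, FALSE = censored).
#' @return object of class `crclot_km` with the fitted curve, median and
#'   95% CI, restricted mean and standard error.
#' @export
km_duration <- function(records) {
  if (nrow(records) == 0) abort("km_duration needs at least one record")
  if (any(records$duration_days < 0)) abort("durations must be nonnegative")
  fit <- survival::survfit(
    survival::Surv(records$duration_days, records$event) ~ 1,
    conf.type = "log-log")
  curve <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, n_censor = fit$n.censor,
                          estimate = fit$surv,
                          conf_low = fit$lower, conf_high = fit$upper)
  med_time <- curve$time[curve$estimate <= 0.5 + 1e-12]
  med <- if (length(med_time) > 0) min(med_time) else NA_real_
  qt <- stats::quantile(fit, probs = 0.5)
  rmean_tbl <- summary(fit, rmean = "common")$table
  rmean <- unname(rmean_tbl[grep("rmean$", names(rmean_tbl))][1])
  rmean_se <- unname(rmean_tbl[grep("se\\(rmean\\)$", names(rmean_tbl))][1])
  largest_censored <- max(records$duration_days) >
    suppressWarnings(max(records$duration_days[records$event], -Inf))
  structure(list(
    fit = fit, curve = curve, n = nrow(records), n_events = sum(records$event),
    median = med,
    median_conf_low = unname(qt$lower[1]),
    median_conf_high = unname(qt$upper[1]),
    rmean = rmean,
    rmean_se = rmean_se,
    largest_censored = largest_censored), class = "crclot_km")
}

#' @export
print.crclot_km <- function(x, ...) {
  cat("Kaplan-Meier duration estimate\n")
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  cat(sprintf("  median = %.1f days (95%% CI %.1f-%.1f)\n",
              x$median, x$median_conf_low, x$median_conf_high))
  cat(sprintf("  restricted mean = %.1f (SE %.2f)%s\n", x$rmean, x$rmean_se,
              if (x$largest_censored) " [largest observation censored: mean underestimated]" else ""))
  invisible(x)
}

model_frame_complete <- function(covariates, terms) {
  x <- covariates[, terms]
  keep <- stats::complete.cases(x)
  list(x = x[keep, ], keep = keep, n_excluded = sum(!keep))
}

wald_tidy <- function(coefs, ses, pvals, exp_scale = TRUE) {
  est <- if (exp_scale) exp(coefs) else coefs
  tibble::tibble(
    term = names(coefs),
    estimate = unname(est),
    conf_low = unname(if (exp_scale) exp(coefs - 1.96 * ses) else coefs - 1.96 * ses),
    conf_high = unname(if (exp_scale) exp(coefs + 1.96 * ses) else coefs + 1.96 * ses),
    p_value = unname(pvals))
}

#' Logistic model for single versus multiple antiangiogenic prescriptions
#'
#' Maximum-likelihood binary logistic regression of the single-prescription
#' outcome (1 vs >= 2 antiangiogenic prescriptions during second-line
#' therapy; coded so that an odds ratio above 1 means higher odds of single
#' use) on the baseline covariate list ([LOGISTIC_TERMS]). Complete-case:
#' rows with missing BMI/ADL are excluded and counted. Separation or
#' non-convergence is flagged, never silently returned as estimates.
#'
#' @param covariates tibble from [build_covariates()].
#' @param outcomes logical vector, `TRUE` = exactly one antiangiogenic
#'   prescription.
#' @return object of class `crclot_logistic` with odds ratios, Wald 95%
#'   CIs and p-values.
#' @export
fit_single_dose_logistic <- function(covariates, outcomes) {
  mf <- model_frame_complete(covariates, LOGISTIC_TERMS)
  y <- outcomes[mf$keep]
  if (length(unique(y)) < 2) {
    abort("separation: the single-use outcome has one level; no finite fit exists")
  }
  dat <- dplyr::mutate(mf$x, dplyr::across(dplyr::everything(), as.numeric))
  dat$.outcome <- as.numeric(y)
  form <- stats::as.formula(paste(".outcome ~", paste(LOGISTIC_TERMS, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = dat))
  sm <- summary(fit)$coefficients
  converged <- fit$converged && all(abs(stats::coef(fit)) < 10, na.rm = TRUE)
  if (!converged) {
    warn("logistic fit flagged non-convergent (possible separation); inspect before use")
  }
  structure(list(
    model = fit,
    estimates = wald_tidy(sm[, "Estimate"], sm[, "Std. Error"], sm[, "Pr(>|z|)"]),
    n_used = sum(mf$keep), n_excluded = mf$n_excluded,
    converged = converged), class = "crclot_logistic")
}

#' Cox model for overall treatment duration from second-line start
#'
#' Proportional-hazards partial-likelihood fit (Efron tie handling — claims
#' data at day granularity is heavily tied) of overall treatment duration
#' from the start of second-line antiangiogenic therapy to the end of all
#' antitumor drug therapy, on the full covariate list ([COVARIATE_TERMS]).
#' The event indicator follows the 60-day completion rule; otherwise the
#' record is censored at the expected final dose date. Complete-case with
#' the exclusion count reported.
#'
#' @param covariates tibble from [build_covariates()].
#' @param records tibble with `duration_days` and `event`, row-aligned with
#'   `covariates`.
#' @return object of class `crclot_cox` with hazard ratios, Wald 95% CIs
#'   and p-values.
#' @export
fit_overall_duration_cox <- function(covariates, records) {
  mf <- model_frame_complete(covariates, COVARIATE_TERMS)
  rec <- records[mf$keep, ]
  if (sum(rec$event) == 0) abort("no events: the Cox model cannot be fitted")
  dat <- dplyr::mutate(mf$x, dplyr::across(dplyr::everything(), as.numeric))
  dat$.time <- rec$duration_days
  dat$.event <- as.numeric(rec$event)
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                  paste(COVARIATE_TERMS, collapse = " + ")))
  fit <- survival::coxph(form, data = dat, ties = "efron")
  sm <- summary(fit)$coefficients
  coefs <- setNames(sm[, "coef"], rownames(sm))
  structure(list(
    model = fit,
    estimates = wald_tidy(coefs, sm[, "se(coef)"], sm[, "Pr(>|z|)"]),
    n_used = sum(mf$keep), n_excluded = mf$n_excluded,
    n_events = sum(rec$event),
    converged = is.null(fit$info) || !isTRUE(fit$info$flag)), class = "crclot_cox")
}

#' @export
print.crclot_logistic <- function(x, ...) {
  cat(sprintf("Logistic model (single vs multiple antiangiogenic doses), n = %d (%d excluded)%s\n",
              x$n_used, x$n_excluded, if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$estimates)
  invisible(x)
}

#' @export
print.crclot_cox <- function(x, ...) {
  cat(sprintf("Cox model (overall treatment duration), n = %d (%d excluded), events = %d\n",
              x$n_used, x$n_excluded, x$n_events))
  print(x$estimates)
  invisible(x)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction, 1 degree of freedom: the statistic is the
#' sum over cells of (observed - expected)^2 / expected with expected
#' counts from the margins.
#'
#' @param a,b,c,d nonnegative integer cell counts, rows = groups, columns =
#'   outcome; all four margins must be positive.
#' @return list with `statistic`, `df` and `p_value`.
#' @export
#' @examples
#' chi_square_2x2(20, 10, 10, 20)
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("cell counts must be nonnegative integers")
  }
  n <- sum(counts)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) abort("all margins of the 2x2 table must be positive")
  expected <- c((a + b) * (a + c), (a + b) * (b + d),
                (c + d) * (a + c), (c + d) * (b + d)) / n
  statistic <- sum((counts - expected)^2 / expected)
  list(statistic = statistic, df = 1L,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE))
}
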