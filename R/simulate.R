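#' Covariate terms used by the statistical stages
#'
#' Fixed term order for the logistic model (first 11 terms) and the Cox
#' model (all 16: the logistic terms plus the five concomitant-exposure
#' flags measured during second-line therapy).
#'
#' @export
COVARIATE_TERMS <- c(
  "designated_cancer_hospital", "age_ge70_at_2l", "male", "left_sided",
  "presumed_ras_wild", "bmi_le_18_5", "adl_not_independent",
  "oral_fp_prev_line", "irinotecan_prev_line", "prev_line_ge180d",
  "early_recurrence",
  "qual_proteinuria_2l", "quant_proteinuria_2l", "antihypertensive_2l",
  "anticholinergic_2l", "anticoagulant_2l"
)

#' @rdname COVARIATE_TERMS
#' @export
LOGISTIC_TERMS <- COVARIATE_TERMS[1:11]

default_cox_log_hr <- function() {
  # a realistic default world: log hazard ratios shaped like the
  # associations the pipeline is designed to estimate
  setNames(c(0.12, 0.06, 0.05, -0.16, -0.45, 0.27, 0.31, -0.22, 0.15,
             -0.09, -0.39, -0.31, -0.11, -0.12, -0.09, -0.06),
           COVARIATE_TERMS)
}

default_logistic_log_or <- function() {
  # odds of a single antiangiogenic dose: raised by old age and dependent
  # ADL, lowered by presumed RAS-wild-type disease and early recurrence
  out <- setNames(rep(0, length(LOGISTIC_TERMS)), LOGISTIC_TERMS)
  out["age_ge70_at_2l"] <- log(1.72)
  out["adl_not_independent"] <- log(2.04)
  out["presumed_ras_wild"] <- log(0.53)
  out["early_recurrence"] <- log(0.50)
  out
}

default_covariate_prevalence <- function() {
  setNames(c(0.74, 0.41, 0.58, 0.69, 0.30, 0.10, 0.09, 0.25, 0.11, 0.45,
             0.09, 0.50, 0.07, 0.21, 0.20, 0.05),
           COVARIATE_TERMS)
}

AA_DOSE <- c(bevacizumab = 350, ramucirumab = 450, aflibercept_beta = 280)
ORAL_DRUGS <- c("capecitabine", "s1", "uft", "ftd_tpi", "regorafenib")

menu_entry <- function(drugs, weight) list(drugs = drugs, weight = weight)

default_regimen_menu <- function() {
  FOLFOX <- c("fluorouracil", "leucovorin", "oxaliplatin")
  FOLFIRI <- c("fluorouracil", "leucovorin", "irinotecan")
  FOLFOXIRI <- c("fluorouracil", "leucovorin", "oxaliplatin", "irinotecan")
  list(
    first_line_mutant = list(
      menu_entry(c(FOLFOX, "bevacizumab"), 0.35),
      menu_entry(c("capecitabine", "oxaliplatin", "bevacizumab"), 0.30),
      menu_entry(c(FOLFIRI, "bevacizumab"), 0.12),
      menu_entry(c("s1", "oxaliplatin", "bevacizumab"), 0.08),
      menu_entry(c(FOLFOXIRI, "bevacizumab"), 0.05),
      menu_entry(c("capecitabine", "bevacizumab"), 0.10)
    ),
    first_line_wild = list(
      menu_entry(c(FOLFOX, "panitumumab"), 0.35),
      menu_entry(c(FOLFOX, "cetuximab"), 0.10),
      menu_entry(c(FOLFOX, "bevacizumab"), 0.15),
      menu_entry(c("capecitabine", "oxaliplatin", "bevacizumab"), 0.15),
      menu_entry(c(FOLFIRI, "panitumumab"), 0.15),
      menu_entry(c(FOLFIRI, "cetuximab"), 0.10)
    ),
    adjuvant = list(
      menu_entry(c("capecitabine", "oxaliplatin"), 0.35),
      menu_entry("capecitabine", 0.25),
      menu_entry("uft", 0.15),
      menu_entry("s1", 0.10),
      menu_entry(FOLFOX, 0.15)
    ),
    second_line_mutant = list(
      menu_entry(c(FOLFIRI, "bevacizumab"), 0.30),
      menu_entry(c(FOLFIRI, "ramucirumab"), 0.20),
      menu_entry(c(FOLFIRI, "aflibercept_beta"), 0.08),
      menu_entry(c("capecitabine", "oxaliplatin", "bevacizumab"), 0.10),
      menu_entry(c(FOLFOX, "bevacizumab"), 0.08),
      menu_entry(c("s1", "irinotecan"), 0.08),
      menu_entry("ftd_tpi", 0.08),
      menu_entry(c("irinotecan", "ramucirumab"), 0.08)
    ),
    second_line_wild = list(
      menu_entry(c(FOLFIRI, "panitumumab"), 0.22),
      menu_entry(c(FOLFIRI, "cetuximab"), 0.10),
      menu_entry(c(FOLFIRI, "bevacizumab"), 0.18),
      menu_entry(c(FOLFIRI, "ramucirumab"), 0.12),
      menu_entry(c(FOLFIRI, "aflibercept_beta"), 0.05),
      menu_entry(c("capecitabine", "oxaliplatin", "bevacizumab"), 0.10),
      menu_entry(c("s1", "irinotecan"), 0.08),
      menu_entry(c(FOLFOX, "panitumumab"), 0.15)
    ),
    later_line = list(
      menu_entry("ftd_tpi", 0.30),
      menu_entry("regorafenib", 0.25),
      menu_entry(FOLFOXIRI, 0.10),
      menu_entry(c("irinotecan", "ramucirumab"), 0.10),
      menu_entry("capecitabine", 0.10),
      menu_entry("pembrolizumab", 0.15)
    )
  )
}

#' Simulation configuration
#'
#' The stated world of the synthetic claims generator. Defaults emulate the
#' study conditions the pipeline targets: enrollment May 2016 - July 2019,
#' roughly 9% early-recurrence patients, 30% presumed RAS-wild-type,
#' transition probabilities near the reported transition rates, biweekly
#' antiangiogenic dosing with occasional >= 7-day delays, ~12% missing
#' BMI/ADL, and covariate-dependent discontinuation through an exponential
#' proportional-hazards mechanism.
#'
#' @param n_patients number of patients to simulate.
#' @param seed RNG seed recorded in the output manifest.
#' @param enrollment_window date pair for therapy start dates.
#' @param p_early_recurrence probability of the early-recurrence pathway.
#' @param p_ras_wildtype probability of intending an anti-EGFR-containing
#'   treatment history.
#' @param line_transition_probs probability of reaching line 2, 3, 4, 5
#'   given the previous line (the adjuvant-to-second transition is 1 by
#'   definition for the early-recurrence pathway).
#' @param regimen_menu per-context weighted regimen sets.
#' @param cycle_jitter_days uniform jitter (+/- days) on repeat doses.
#' @param p_interval_delay probability that an antiangiogenic interval is
#'   delayed beyond the biweekly schedule.
#' @param delay_days delay range in days when a delay occurs.
#' @param p_biologic_addition probability that a single-biologic regimen in
#'   lines >= 2 has its biologic started after the 28-day window (a regimen
#'   addition rather than a base drug).
#' @param p_dose_reduction probability of an antiangiogenic dose reduction.
#' @param missing_bmi,missing_adl probability a patient has no BMI/Barthel
#'   assessments at all.
#' @param baseline_hazard exponential baseline hazard (per day) for overall
#'   treatment duration from second-line start.
#' @param cox_log_hr named log-hazard-ratio vector over [COVARIATE_TERMS].
#' @param logistic_intercept,logistic_log_or intercept and named log-odds-
#'   ratio vector (over [LOGISTIC_TERMS]) for the single-dose outcome.
#' @param data_end_lag_days range of the uniform lag between a patient's
#'   last claim and the hospital's data-availability end.
#' @param covariate_prevalence marginal prevalences used when covariates are
#'   drawn freely (standalone outcome simulation).
#' @param noise_free convenience switch: zero jitter, zero interval delays,
#'   zero missingness (ground-truth recovery conditions).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500L,
                       seed = 20160501L,
                       enrollment_window = as.Date(c("2016-05-01", "2019-07-31")),
                       p_early_recurrence = 0.09,
                       p_ras_wildtype = 0.30,
                       line_transition_probs = c(0.60, 0.60, 0.55, 0.50),
                       regimen_menu = default_regimen_menu(),
                       cycle_jitter_days = 2L,
                       p_interval_delay = 0.20,
                       delay_days = c(7L, 28L),
                       p_biologic_addition = 0.15,
                       p_dose_reduction = 0.12,
                       missing_bmi = 0.12,
                       missing_adl = 0.12,
                       baseline_hazard = log(2) / 240,
                       cox_log_hr = default_cox_log_hr(),
                       logistic_intercept = stats::qlogis(0.10),
                       logistic_log_or = default_logistic_log_or(),
                       data_end_lag_days = c(0L, 400L),
                       covariate_prevalence = default_covariate_prevalence(),
                       noise_free = FALSE) {
  if (noise_free) {
    cycle_jitter_days <- 0L
    p_interval_delay <- 0
    missing_bmi <- 0
    missing_adl <- 0
  }
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              enrollment_window = as_iso_date(enrollment_window),
              p_early_recurrence = p_early_recurrence,
              p_ras_wildtype = p_ras_wildtype,
              line_transition_probs = line_transition_probs,
              regimen_menu = regimen_menu,
              cycle_jitter_days = as.integer(cycle_jitter_days),
              p_interval_delay = p_interval_delay,
              delay_days = as.integer(delay_days),
              p_biologic_addition = p_biologic_addition,
              p_dose_reduction = p_dose_reduction,
              missing_bmi = missing_bmi, missing_adl = missing_adl,
              baseline_hazard = baseline_hazard,
              cox_log_hr = cox_log_hr,
              logistic_intercept = logistic_intercept,
              logistic_log_or = logistic_log_or,
              data_end_lag_days = as.integer(data_end_lag_days),
              covariate_prevalence = covariate_prevalence,
              noise_free = noise_free)
  probs <- c(cfg$p_early_recurrence, cfg$p_ras_wildtype, cfg$line_transition_probs,
             cfg$p_interval_delay, cfg$p_biologic_addition, cfg$p_dose_reduction,
             cfg$missing_bmi, cfg$missing_adl, cfg$covariate_prevalence)
  if (any(probs < 0 | probs > 1)) abort("config error: probabilities must lie in [0, 1]")
  if (cfg$n_patients < 0) abort("config error: n_patients must be >= 0")
  if (days_between(cfg$enrollment_window[1], cfg$enrollment_window[2]) < 28) {
    abort("config error: enrollment window shorter than one 28-day cycle")
  }
  for (menu in cfg$regimen_menu) {
    w <- vapply(menu, function(e) e$weight, numeric(1))
    if (any(w < 0) || sum(w) <= 0) abort("config error: menu weights must be nonnegative and normalisable")
  }
  if (cfg$baseline_hazard <= 0) abort("config error: baseline hazard must be positive")
  structure(cfg, class = "sim_config")
}

sample_menu <- function(menu) {
  w <- vapply(menu, function(e) e$weight, numeric(1))
  menu[[sample.int(length(menu), 1, prob = w)]]$drugs
}

#' Simulate covariates and outcomes from the generator's mechanisms
#'
#' Draws covariate vectors from their marginal prevalences, the single-dose
#' outcome from the logistic mechanism, and overall treatment duration from
#' the exponential proportional-hazards mechanism with independent uniform
#' censoring-lag. This is the same mechanism [simulate_bundle()] uses for
#' its ground-truth outcomes, exposed directly so parameter-recovery
#' properties can be checked at large n without building claims tables.
#'
#' @param n number of subjects.
#' @param config a [sim_config()].
#' @return tibble with one column per [COVARIATE_TERMS] (logical), plus
#'   `single_use` (logical), `duration_days` (integer) and `event` (logical).
#' @export
simulate_outcomes <- function(n, config = sim_config()) {
  prev <- config$covariate_prevalence[COVARIATE_TERMS]
  x <- purrr::map(prev, ~ stats::runif(n) < .x) |> tibble::as_tibble()
  x$single_use <- stats::runif(n) < plogis_linpred(x, config)
  rate <- config$baseline_hazard * exp(cox_linpred(x, config))
  duration <- pmax(1L, as.integer(round(stats::rexp(n, rate))))
  lag <- stats::runif(n, config$data_end_lag_days[1], config$data_end_lag_days[2])
  x$duration_days <- duration
  x$event <- lag >= 60
  x
}

plogis_linpred <- function(x, config) {
  lp <- config$logistic_intercept
  for (term in LOGISTIC_TERMS) {
    lp <- lp + config$logistic_log_or[[term]] * as.numeric(x[[term]])
  }
  stats::plogis(lp)
}

cox_linpred <- function(x, config) {
  lp <- 0
  for (term in COVARIATE_TERMS) {
    lp <- lp + config$cox_log_hr[[term]] * as.numeric(x[[term]])
  }
  lp
}

# ---- claims emission helpers -------------------------------------------

# repeat prescriptions of one drug over a line: first dose on `start`,
# repeats on the drug cycle +/- jitter, last covered dose at start+D-cycle
drug_schedule <- function(start, duration, cycle, jitter) {
  ks <- seq(0L, max(0L, duration - cycle), by = cycle)
  dates <- start + ks
  if (jitter > 0 && length(dates) > 1) {
    shift <- sample(seq(-jitter, jitter), length(dates) - 1, replace = TRUE)
    dates[-1] <- pmin(pmax(dates[-1] + shift, start + 1L), start + duration - 1L)
  }
  sort(dates)
}

# antiangiogenic schedule with occasional delayed intervals (>= 7 days past
# the biweekly schedule, so prescription gaps of >= 21 days)
aa_schedule <- function(start, duration, config) {
  dates <- start
  t <- start
  repeat {
    step <- 14L
    if (stats::runif(1) < config$p_interval_delay) {
      step <- step + sample(seq(config$delay_days[1], config$delay_days[2]), 1)
    }
    t <- t + step
    if (days_between(start, t) > duration - 14L) break
    dates <- c(dates, t)
  }
  dates
}

barthel_items_for_total <- function(total) {
  items <- BARTHEL_ITEM_MAX
  deficit <- 100L - total
  i <- 1L
  while (deficit > 0) {
    take <- min(items[i], deficit)
    items[i] <- items[i] - take
    deficit <- deficit - take
    i <- i + 1L
  }
  paste(items, collapse = ";")
}

SIDED_LEFT_CODES <- c("C18.7", "C19", "C20")
SIDED_RIGHT_CODES <- c("C18.0", "C18.2", "C18.3", "C18.4")

#' Simulate a synthetic claims bundle with ground truth
#'
#' Generates per-patient treatment histories (diagnoses, prescriptions,
#' procedures, assessments, hospital attributes) whose latent line structure
#' is known, then writes them as claims. The generator emits prescriptions,
#' not lines: the line structure must be recovered by [derive_lines()],
#' making the derivation algorithm the thing under test. Under
#' `noise_free = TRUE` the derived lines match the truth lines exactly.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list with `bundle` (a `claims_bundle`), `truth` (list of
#'   `patients` and `lines` tibbles) and `manifest` (seed and key
#'   configuration echoed for reproducibility).
#' @export
simulate_bundle <- function(config = sim_config(), seed = NULL) {
  seed <- as.integer(seed %||% config$seed)
  set.seed(seed)
  n <- config$n_patients

  n_hosp <- max(3L, as.integer(round(n / 40)))
  hospitals <- tibble::tibble(
    hospital_id = sprintf("H%03d", seq_len(n_hosp)),
    bed_class = sample(c("<200", "200-499", ">=500"), n_hosp, replace = TRUE,
                       prob = c(0.06, 0.57, 0.37)),
    designated_cancer = stats::runif(n_hosp) <
      config$covariate_prevalence[["designated_cancer_hospital"]]
  )

  vocab <- drug_vocabulary()
  out <- purrr::map(seq_len(n), function(i) {
    simulate_patient(sprintf("P%05d", i), hospitals, config, vocab)
  })

  gather <- function(part) {
    dplyr::bind_rows(empty_bundle_table(part), purrr::map(out, part_name(part)))
  }
  part_name <- function(part) if (part == "patients") "patient" else part
  bundle <- claims_bundle(
    patients = gather("patients"),
    hospitals = hospitals,
    diagnoses = gather("diagnoses"),
    prescriptions = gather("prescriptions"),
    procedures = gather("procedures"),
    assessments = gather("assessments")
  )
  truth <- list(patients = dplyr::bind_rows(purrr::map(out, "truth_patient")),
                lines = dplyr::bind_rows(purrr::map(out, "truth_lines")))
  manifest <- list(seed = seed, n_patients = n, noise_free = config$noise_free,
                   generated_at_version = as.character(utils::packageVersion("crclot")))
  list(bundle = bundle, truth = truth, manifest = manifest)
}

#' Ground-truth therapy lines for one patient
#'
#' @param truth the `truth` component of [simulate_bundle()] output.
#' @param patient_id one patient id.
#' @return the patient's true lines, ordered by line start.
#' @export
truth_lines <- function(truth, patient_id) {
  if (!patient_id %in% truth$patients$patient_id) {
    abort(paste0("unknown patient in truth: ", patient_id))
  }
  out <- truth$lines[truth$lines$patient_id == patient_id, ]
  dplyr::arrange(out, .data$start_date)
}
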