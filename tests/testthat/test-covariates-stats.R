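test_that("covariate construction follows the baseline and second-line windows", {
  rx <- dplyr::bind_rows(
    rx_block("P1", seq(0, 42, 21), c("capecitabine", "oxaliplatin")),
    fx_rx("P1", day(0), "bevacizumab"),
    rx_block("P1", seq(150, 192, 14), c(FOLFIRI, "ramucirumab")),
    fx_rx("P1", day(150), "amlodipine", route = "oral"),
    fx_rx("P1", day(149), "warfarin", route = "oral")) # day before line 2
  b <- fx_bundle(
    fx_patients("P1", birth_year = 1945L),
    diagnoses = dplyr::bind_rows(
      fx_dx("P1", day(-30), "C18.2"),
      fx_dx("P1", day(-30), "C20"),
      fx_dx("P1", day(-30), "C18.4", confirmed = FALSE)),
    prescriptions = rx,
    procedures = tibble::tibble(patient_id = "P1", date = day(150),
                                kind = "proteinuria_qualitative"),
    assessments = tibble::tibble(
      patient_id = "P1", date = day(c(0, 140)), kind = "bmi",
      value = c(17.9, 22.0), items = NA_character_))
  members <- tibble::tibble(
    patient_id = "P1", population = "first_line", anchor_date = day(0),
    therapy_start_date = day(0), index_date = as.Date(NA),
    presumed_ras = "mutant")
  lines <- derive_lines_bundle(b, members)
  members <- assign_index_dates(members, lines)
  cv <- build_covariates(b, members, lines)

  expect_true(cv$right_sided)  # C18.2 confirmed
  expect_true(cv$left_sided)   # C20 confirmed: both flags may hold at once
  expect_true(cv$age_ge70_at_2l)
  expect_true(cv$oral_fp_prev_line)     # CAPOX has oral capecitabine
  expect_false(cv$irinotecan_prev_line) # irinotecan only in line 2
  expect_false(cv$prev_line_ge180d)     # line 1 spans 150 days
  expect_false(cv$bmi_le_18_5)          # latest baseline BMI (22.0) wins
  expect_false(cv$bmi_missing)
  expect_true(cv$adl_missing)           # no Barthel assessment at all
  expect_true(is.na(cv$adl_not_independent))
  expect_true(cv$antihypertensive_2l)   # amlodipine on the index day
  expect_false(cv$anticoagulant_2l)     # warfarin the day before line 2
  expect_true(cv$qual_proteinuria_2l)
  expect_false(cv$quant_proteinuria_2l)

  expect_error(build_covariates(b, dplyr::mutate(members, index_date = as.Date(NA)), lines),
               "index_date")
})

test_that("a full Barthel score means independent ADL", {
  mk <- function(total) {
    b <- fx_bundle(
      fx_patients("P1"),
      prescriptions = dplyr::bind_rows(
        rx_block("P1", 0, c("capecitabine", "bevacizumab")),
        rx_block("P1", 100, FOLFIRI)),
      assessments = tibble::tibble(patient_id = "P1", date = day(90),
                                   kind = "barthel", value = total,
                                   items = NA_character_))
    members <- tibble::tibble(
      patient_id = "P1", population = "first_line", anchor_date = day(0),
      therapy_start_date = day(0), index_date = day(100), presumed_ras = "mutant")
    lines <- derive_lines_bundle(b, members)
    build_covariates(b, members, lines)
  }
  expect_false(mk(100)$adl_not_independent)
  expect_true(mk(95)$adl_not_independent)
})

test_that("the product-limit estimate matches closed forms and the brute-force oracle", {
  km <- km_duration(tibble::tibble(duration_days = c(2, 4, 6, 8, 10),
                                   event = TRUE))
  expect_equal(km$median, 6)
  expect_equal(km_duration(tibble::tibble(duration_days = c(5, 5, 5),
                                          event = TRUE))$median, 5)

  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    rec <- tibble::tibble(duration_days = sample(1:60, n, replace = TRUE),
                          event = stats::runif(n) < 0.7)
    if (!any(rec$event)) rec$event[1] <- TRUE
    km <- km_duration(rec)
    oracle <- km_oracle(rec$duration_days, rec$event)
    got <- km$curve[km$curve$n_event > 0, c("time", "estimate")]
    expect_equal(got$time, oracle$time)
    expect_equal(got$estimate, oracle$estimate, tolerance = 1e-12)
  }

  degenerate <- km_duration(tibble::tibble(duration_days = c(0, 0), event = TRUE))
  expect_equal(degenerate$median, 0)
  cens <- km_duration(tibble::tibble(duration_days = c(3, 9), event = c(TRUE, FALSE)))
  expect_true(cens$largest_censored)
})

covariate_frame <- function(n, active, values) {
  x <- tibble::as_tibble(setNames(
    purrr::map(COVARIATE_TERMS, ~ rep(FALSE, n)), COVARIATE_TERMS))
  x[[active]] <- values
  x
}

test_that("logistic fit recovers a 2x2 layout exactly and flags degeneracy", {
  # (a, b; c, d) = (10, 40; 20, 80): proportional rows, odds ratio exactly 1
  n <- 10 + 40 + 20 + 80
  x <- covariate_frame(n, "male", rep(c(TRUE, FALSE), c(50, 100)))
  y <- c(rep(c(TRUE, FALSE), c(10, 40)), rep(c(TRUE, FALSE), c(20, 80)))
  fit <- fit_single_dose_logistic(x, y)
  expect_equal(tidy(fit)$estimate[tidy(fit)$term == "male"], 1.0,
               tolerance = 1e-8)
  expect_equal(glance(fit)$n_used, n)

  expect_error(fit_single_dose_logistic(x, rep(FALSE, n)), "separation")
})

test_that("complete-case handling drops and counts rows with missing BMI/ADL", {
  n <- 60
  x <- covariate_frame(n, "male", rep(c(TRUE, FALSE), each = 30))
  x$bmi_le_18_5[1:7] <- NA
  y <- rep(c(TRUE, FALSE), n / 2)
  fit <- fit_single_dose_logistic(x, y)
  expect_equal(fit$n_used, n - 7)
  expect_equal(fit$n_excluded, 7)
})

test_that("the Cox stage recovers a two-group exponential rate ratio", {
  set.seed(91)
  n <- 1000
  grp <- rep(c(TRUE, FALSE), each = n / 2)
  x <- covariate_frame(n, "bmi_le_18_5", grp)
  rec <- tibble::tibble(
    duration_days = round(stats::rexp(n, rate = ifelse(grp, 2, 1) / 200)) + 1,
    event = TRUE)
  fit <- fit_overall_duration_cox(x, rec)
  hr <- tidy(fit)$estimate[tidy(fit)$term == "bmi_le_18_5"]
  expect_gt(hr, 1.7)
  expect_lt(hr, 2.3)
  expect_equal(glance(fit)$n_events, n)

  expect_error(fit_overall_duration_cox(x, dplyr::mutate(rec, event = FALSE)),
               "no events")
})

test_that("the 2x2 chi-square matches the expected-count formula", {
  flat <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  # hand computation: all expected counts 15, sum(25/15 * 4) = 20/3
  hand <- chi_square_2x2(20, 10, 10, 20)
  expect_equal(hand$statistic, 20 / 3, tolerance = 1e-12)
  ref <- stats::chisq.test(matrix(c(20, 10, 10, 20), 2), correct = FALSE)
  expect_equal(hand$statistic, unname(ref$statistic))
  expect_equal(hand$p_value, unname(ref$p.value))

  extreme <- chi_square_2x2(0, 5, 5, 0)
  expect_gt(extreme$statistic, 6)
  expect_lt(extreme$p_value, 0.01)

  expect_error(chi_square_2x2(0, 0, 5, 5), "margins")
  expect_error(chi_square_2x2(1.5, 2, 3, 4), "integers")
})

test_that("derived covariates match the generator's truth on noise-free data", {
  sim <- simulate_bundle(sim_config(n_patients = 120, noise_free = TRUE, seed = 17))
  m <- select_cohorts(sim$bundle)$members
  lines <- derive_lines_bundle(sim$bundle, m)
  m <- assign_index_dates(m, lines)
  with2 <- m[!is.na(m$index_date), ]
  cv <- build_covariates(sim$bundle, with2, lines)
  tr <- sim$truth$patients[match(with2$patient_id, sim$truth$patients$patient_id), ]
  for (term in COVARIATE_TERMS) {
    mismatch <- sum(cv[[term]] != tr[[term]], na.rm = TRUE)
    expect_equal(mismatch, 0, info = term)
    expect_equal(is.na(cv[[term]]), is.na(tr[[term]]) |
                   (term == "bmi_le_18_5" & tr$bmi_missing) |
                   (term == "adl_not_independent" & tr$adl_missing),
                 info = term)
  }
})
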