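# Cohort windows are calendar-based; these fixtures use real study-period
# dates rather than the day() origin shortcuts.
cfg <- cohort_config()

test_that("first CRC diagnosis takes the earliest confirmed C18-C20 code in window", {
  b <- fx_bundle(fx_patients("P1"), diagnoses = dplyr::bind_rows(
    fx_dx("P1", as.Date("2016-01-10"), "C18.2"),
    fx_dx("P1", as.Date("2015-06-01"), "C20")))
  expect_equal(first_crc_diagnosis(b, "P1", cfg), as.Date("2015-06-01"))

  b2 <- fx_bundle(fx_patients("P2"), diagnoses = fx_dx("P2", as.Date("2016-01-10"), "C17"))
  expect_true(is.na(first_crc_diagnosis(b2, "P2", cfg)))

  b3 <- fx_bundle(fx_patients("P3"),
                  diagnoses = fx_dx("P3", as.Date("2016-01-10"), "C19",
                                    confirmed = FALSE))
  expect_true(is.na(first_crc_diagnosis(b3, "P3", cfg)))
})

test_that("first-line selection admits a clean anchor and logs attrition", {
  sel <- select_first_line_population(first_line_fixture(), cfg)
  expect_equal(sel$members$patient_id, "P1")
  expect_equal(sel$members$anchor_date, as.Date("2017-03-01"))
  expect_equal(sel$members$therapy_start_date, as.Date("2017-03-01"))
  expect_true(all(diff(sel$log$n_remaining) <= 0))
})

test_that("the one-year antibody washout excludes prior-antibody patients", {
  prior <- fx_rx("P1", as.Date("2016-08-01"), "cetuximab")
  sel <- select_first_line_population(first_line_fixture(prior), cfg)
  expect_equal(nrow(sel$members), 0)
  # boundary pair: exactly 365 days before the anchor excludes, 366 admits
  at365 <- fx_rx("P1", as.Date("2017-03-01") - 365, "bevacizumab")
  expect_equal(nrow(select_first_line_population(first_line_fixture(at365), cfg)$members), 0)
  at366 <- fx_rx("P1", as.Date("2017-03-01") - 366, "bevacizumab")
  # an antibody 366 days before is outside the washout, but then IT becomes
  # the first qualifying anchor (still after diagnosis? no - before it), so
  # the 2017 prescription stays the anchor and the patient is admitted
  expect_equal(nrow(select_first_line_population(first_line_fixture(at366), cfg)$members), 1)
})

test_that("age under 20 at the anchor excludes", {
  sel <- select_first_line_population(first_line_fixture(birth_year = 1998L), cfg)
  expect_equal(nrow(sel$members), 0) # age 19 on 2017-03-01 (July-1 birthday)
  sel20 <- select_first_line_population(first_line_fixture(birth_year = 1996L), cfg)
  expect_equal(nrow(sel20$members), 1)
})

test_that("non-guideline antitumor drugs exclude from selection", {
  off <- fx_rx("P1", as.Date("2018-01-01"), "gemcitabine")
  sel <- select_first_line_population(first_line_fixture(off), cfg)
  expect_equal(nrow(sel$members), 0)
})

test_that("early-recurrence selection follows the surgery/adjuvant/switch windows", {
  # adjuvant day 30 post-surgery, last capecitabine day 150 (post-surgery),
  # covered to day 171; switch day 240: 240 - 171 <= 183 -> included
  sel <- select_early_recurrence_population(er_fixture(), cfg)
  expect_equal(sel$members$population, "early_recurrence")
  expect_equal(sel$members$anchor_date, as.Date("2017-02-01"))
  expect_equal(sel$members$therapy_start_date, as.Date("2017-02-01") + 30)

  # adjuvant started more than 3 months (91 days) after surgery -> excluded
  expect_equal(nrow(select_early_recurrence_population(er_fixture(adjuvant_offset = 92), cfg)$members), 0)
  expect_equal(nrow(select_early_recurrence_population(er_fixture(adjuvant_offset = 91), cfg)$members), 1)

  # switch window boundary: last covered dose day 30+120+21 = 171 after
  # surgery; 171 + 183 = 354 is the last admissible switch day
  expect_equal(nrow(select_early_recurrence_population(er_fixture(switch_offset = 354), cfg)$members), 1)
  expect_equal(nrow(select_early_recurrence_population(er_fixture(switch_offset = 355), cfg)$members), 0)
})

test_that("a biologic added within 3 months of adjuvant start excludes", {
  bev <- fx_rx("P1", as.Date("2017-02-01") + 30 + 60, "bevacizumab")
  expect_equal(nrow(select_early_recurrence_population(er_fixture(extra_rx = bev), cfg)$members), 0)
  # and any biologic before the resection excludes
  pre <- fx_rx("P1", as.Date("2017-01-15"), "bevacizumab")
  expect_equal(nrow(select_early_recurrence_population(er_fixture(extra_rx = pre), cfg)$members), 0)
})

test_that("early-recurrence-eligible patients are excluded from first-line", {
  b <- er_fixture()
  fl <- select_first_line_population(b, cfg)
  er <- select_early_recurrence_population(b, cfg)
  expect_equal(nrow(fl$members), 0)
  expect_equal(nrow(er$members), 1)
})

test_that("presumed RAS status follows any-time anti-EGFR use in window", {
  rx <- dplyr::bind_rows(
    fx_rx("P1", as.Date("2019-05-01"), "panitumumab"),
    fx_rx("P2", as.Date("2018-01-01"), c("bevacizumab", "ramucirumab")),
    fx_rx("P3", as.Date("2019-10-15"), "cetuximab"))
  b <- fx_bundle(fx_patients(c("P1", "P2", "P3"), data_end = as.Date("2020-06-30")),
                 prescriptions = rx)
  expect_equal(presume_ras_status(b, c("P1", "P2", "P3"), cfg$analysis_window),
               c("wild_type", "mutant", "mutant"))
})

test_that("the FOLFIRI plus antiangiogenic subpopulation rule checks the 28-day window", {
  mk <- function(pid, second_drugs, extra = NULL) {
    dplyr::bind_rows(
      rx_block(pid, seq(0, 42, 14), c(FOLFOX, "bevacizumab")),
      rx_block(pid, seq(150, 192, 14), second_drugs),
      extra)
  }
  rx <- dplyr::bind_rows(
    mk("P1", c(FOLFIRI, "ramucirumab")),
    mk("P2", c("capecitabine", "oxaliplatin", "bevacizumab")),
    mk("P3", FOLFIRI, fx_rx("P3", day(c(150, 164)), "bevacizumab")) |>
      dplyr::bind_rows(fx_rx("P3", day(164), "ramucirumab")))
  b <- fx_bundle(fx_patients(c("P1", "P2", "P3")),
                 diagnoses = dplyr::bind_rows(purrr::map(c("P1", "P2", "P3"), fx_eligible_dx)),
                 prescriptions = rx)
  members <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"), population = "first_line",
    anchor_date = day(0), therapy_start_date = day(0),
    index_date = as.Date(NA), presumed_ras = "mutant",
    in_folfiri_aa_subpop = FALSE, second_line_aa_drug = NA_character_,
    multi_aa = FALSE)
  lines <- derive_lines_bundle(b, members)
  members <- assign_index_dates(members, lines)
  members <- select_folfiri_aa_subpopulation(members, lines, b)

  expect_equal(members$in_folfiri_aa_subpop, c(TRUE, FALSE, TRUE))
  expect_equal(members$second_line_aa_drug, c("ramucirumab", NA, "bevacizumab"))
  # P3 had bevacizumab and ramucirumab in the window: earliest wins, flagged
  expect_true(members$multi_aa[3])
  expect_equal(members$index_date, day(c(150, 150, 150)))
})
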