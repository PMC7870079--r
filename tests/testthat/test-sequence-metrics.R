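test_that("the reporting rounding rule is half-up to one decimal", {
  expect_equal(round_half_up(c(11.645, 11.65, 2.45, -2.45), 1),
               c(11.6, 11.7, 2.5, -2.5))
  expect_equal(rate_percent(1, 3), 33.3)
  expect_equal(rate_percent(2, 3), 66.7)
  expect_true(is.na(rate_percent(0, 0)))
})

fabricate_lines <- function(df) {
  # minimal lines rows for transition_rates: one row per patient per line
  tibble::tibble(
    patient_id = df$patient_id, line_number = df$line_number,
    line_label = as.character(df$line_number),
    evaluable_for_transition = df$evaluable, transitioned = df$transitioned)
}

test_that("transition rates count evaluable and transitioned patients", {
  # 7 patients in line 1: 4 transition, 1 has exactly 60 days of margin
  # (not evaluable), 2 are evaluable non-transitions
  df <- tibble::tibble(
    patient_id = sprintf("P%d", 1:7), line_number = 1L,
    evaluable = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    transitioned = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  cohorts <- tibble::tibble(patient_id = df$patient_id,
                            population = "first_line", presumed_ras = "mutant")
  rates <- transition_rates(fabricate_lines(df), cohorts)
  expect_equal(rates$n_evaluable, 6)
  expect_equal(rates$n_transitioned, 4)
  expect_equal(rates$rate_percent, 66.7)
})

test_that("zero evaluable patients report an absent rate, and the adjuvant
           pair is excluded for early recurrence", {
  df <- tibble::tibble(
    patient_id = c("A", "A", "B"), line_number = c(0L, 2L, 0L),
    evaluable = c(TRUE, TRUE, TRUE), transitioned = c(TRUE, FALSE, TRUE))
  lines <- fabricate_lines(df)
  cohorts <- tibble::tibble(patient_id = c("A", "B"),
                            population = "early_recurrence", presumed_ras = "mutant")
  rates <- transition_rates(lines, cohorts)
  # adjuvant (line 0) rows never appear for the early-recurrence stratum
  expect_false(any(rates$from_line == "adjuvant"))
  expect_equal(rates$from_line, "2")
  expect_equal(rates$n_evaluable, 1)

  none <- transition_rates(fabricate_lines(df[df$line_number == 99, ]), cohorts)
  expect_equal(nrow(none), 0)
})

test_that("sequence tables count regimen labels and group flows", {
  mk <- function(pid, l1, l2) {
    dplyr::bind_rows(
      rx_block(pid, seq(0, 42, 14), l1),
      rx_block(pid, seq(150, 192, 14), l2))
  }
  rx <- dplyr::bind_rows(
    mk("P1", c(FOLFOX, "bevacizumab"), c(FOLFIRI, "ramucirumab")),
    mk("P2", c(FOLFOX, "bevacizumab"), c(FOLFIRI, "ramucirumab")),
    mk("P3", c("capecitabine", "oxaliplatin", "bevacizumab"), FOLFIRI))
  b <- fx_bundle(fx_patients(c("P1", "P2", "P3")), prescriptions = rx)
  cohorts <- tibble::tibble(
    patient_id = c("P1", "P2", "P3"), population = "first_line",
    anchor_date = day(0), therapy_start_date = day(0),
    presumed_ras = "mutant")
  lines <- derive_lines_bundle(b, cohorts)
  tab <- sequence_table(lines, cohorts)

  line1 <- tab$regimens[tab$regimens$line_number == 1L, ]
  expect_equal(line1$n[line1$regimen_label == "FOLFOX+BEV"], 2)
  expect_equal(line1$n[line1$regimen_label == "CAPOX+BEV"], 1)
  # all three flows are oxaliplatin-based -> irinotecan-based
  flow <- tab$flows[tab$flows$line_number == 1L, ]
  expect_equal(flow$from_group, "oxaliplatin_based")
  expect_equal(flow$to_group, "irinotecan_based")
  expect_equal(flow$n, 3)

  empty <- sequence_table(lines[0, ], cohorts)
  expect_equal(nrow(empty$regimens), 0)
})

test_that("second-line antiangiogenic report captures gaps, single use and dose cuts", {
  schedule <- list(
    P1 = list(offsets = c(0, 14, 42), dose = c(400, 400, 400)),   # gap 28
    P2 = list(offsets = 0, dose = 400),                           # single use
    P3 = list(offsets = c(0, 14), dose = c(400, 300)),            # reduction
    P4 = list(offsets = c(0, 14, 28), dose = c(400, 400, 400)))
  rx <- purrr::imap(schedule, function(s, pid) {
    dplyr::bind_rows(
      rx_block(pid, seq(0, 42, 14), c(FOLFOX, "bevacizumab")),
      rx_block(pid, 150 + s$offsets, FOLFIRI),
      fx_rx(pid, day(150 + s$offsets), "ramucirumab", dose = s$dose))
  }) |> dplyr::bind_rows()
  b <- fx_bundle(fx_patients(names(schedule), data_end = day(400)),
                 prescriptions = rx)
  cohorts <- tibble::tibble(
    patient_id = names(schedule), population = "first_line",
    anchor_date = day(0), therapy_start_date = day(0), presumed_ras = "mutant")
  lines <- derive_lines_bundle(b, cohorts)
  cohorts <- assign_index_dates(cohorts, lines)
  cohorts <- select_folfiri_aa_subpopulation(cohorts, lines, b)
  expect_true(all(cohorts$in_folfiri_aa_subpop))

  res <- second_line_aa_report(lines, cohorts, b)
  d <- res$patients[order(res$patients$patient_id), ]
  expect_equal(d$n_aa_prescriptions, c(3L, 1L, 2L, 3L))
  expect_equal(d$gap_ge21, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(d$single_use, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(d$dose_reduced, c(FALSE, FALSE, TRUE, FALSE))

  overall <- res$report[res$report$stratum == "overall", ]
  expect_equal(overall$n_subpop, 4L)
  expect_equal(overall$n_single_use, sum(d$single_use[d$evaluable]))
  # per-drug strata partition the overall counts
  per_drug <- res$report[res$report$stratum != "overall", ]
  expect_equal(sum(per_drug$n_subpop), overall$n_subpop)

  none <- second_line_aa_report(lines, dplyr::mutate(cohorts, in_folfiri_aa_subpop = FALSE), b)
  expect_equal(nrow(none$report), 0)
})
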