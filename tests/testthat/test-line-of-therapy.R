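test_that("expected final dose date uses supply when present, cycle otherwise", {
  rx <- tibble::tibble(date = day(c(100, 50)),
                       drug_id = c("bevacizumab", "capecitabine"),
                       days_supplied = c(NA_integer_, 21L))
  expect_equal(expected_final_dose_date(rx), day(c(114, 71)))
  expect_error(
    expected_final_dose_date(tibble::tibble(date = day(10), drug_id = "amlodipine")),
    "antitumor")
})

test_that("regimen assembly takes exactly the initial 28-day window", {
  rx <- dplyr::bind_rows(
    rx_block("P1", 0, FOLFOX),
    fx_rx("P1", day(14), "bevacizumab"),
    fx_rx("P1", day(27), "irinotecan"),
    fx_rx("P1", day(28), "ramucirumab"))
  r <- assemble_regimen(rx, day(0))
  expect_setequal(r$raw_drug_set[[1]],
                  c(FOLFOX, "bevacizumab", "irinotecan"))
  expect_false("ramucirumab" %in% r$raw_drug_set[[1]]) # day 28 is outside
  expect_error(assemble_regimen(fx_rx("P1", day(40), "bevacizumab"), day(0)),
               "28-day window")
})

test_that("new-drug rule ends a line at the new prescription's date", {
  rx <- dplyr::bind_rows(
    rx_block("P1", seq(0, 84, 14), c(FOLFOX, "bevacizumab")),
    rx_block("P1", seq(200, 242, 14), c(FOLFIRI, "ramucirumab")))
  lines <- derive_lines(rx, day(0), data_end = day(500), patient_id = "P1")
  expect_equal(nrow(lines), 2)
  expect_equal(lines$end_reason, c("new_drug", "data_end"))
  expect_equal(lines$start_date, day(c(0, 200)))
  expect_equal(lines$end_date[1], day(200))
  expect_equal(lines$regimen_label, c("FOLFOX+BEV", "FOLFIRI+RAM"))
  expect_equal(lines$duration_days[1], 200L)
  # partition: every antitumor prescription belongs to exactly one line
  expect_equal(sum(lines$n_prescriptions), nrow(rx))
})

test_that("a 180-day gap ends a line at its running expected final dose date", {
  # adjuvant CAPOX, last dose day 63 (capecitabine covers to day 84), then
  # the identical regimen restarts on day 300: 300 - 84 >= 180, so the
  # restart is a new line even with the same drugs
  rx <- dplyr::bind_rows(
    rx_block("P1", seq(0, 63, 21), c("capecitabine", "oxaliplatin")),
    rx_block("P1", 300, c("capecitabine", "oxaliplatin")))
  lines <- derive_lines(rx, day(0), data_end = day(600),
                        first_line_number = 0L, patient_id = "P1")
  expect_equal(lines$end_reason, c("gap_180", "data_end"))
  expect_equal(lines$end_date[1], day(84))
  expect_equal(lines$line_number, c(0L, 2L))

  # boundary pair: 179-day interval continues the same line
  rx179 <- dplyr::bind_rows(
    rx_block("P1", seq(0, 63, 21), c("capecitabine", "oxaliplatin")),
    rx_block("P1", 84 + 179, c("capecitabine", "oxaliplatin")))
  expect_equal(nrow(derive_lines(rx179, day(0), data_end = day(600),
                                 first_line_number = 0L)), 1)
  rx180 <- dplyr::bind_rows(
    rx_block("P1", seq(0, 63, 21), c("capecitabine", "oxaliplatin")),
    rx_block("P1", 84 + 180, c("capecitabine", "oxaliplatin")))
  expect_equal(nrow(derive_lines(rx180, day(0), data_end = day(600),
                                 first_line_number = 0L)), 2)
})

test_that("biologics added to chemotherapy-only later lines extend the regimen", {
  # line 1 anchored at bevacizumab; line 2 starts FOLFIRI alone, bevacizumab
  # returns on day 128 (outside the window) -> addition, not a new line
  rx <- dplyr::bind_rows(
    rx_block("P1", seq(0, 42, 14), c("capecitabine", "bevacizumab")),
    rx_block("P1", seq(100, 170, 14), FOLFIRI),
    fx_rx("P1", day(c(128, 142, 156, 170)), "bevacizumab"))
  lines <- derive_lines(rx, day(0), data_end = day(400), patient_id = "P1")
  expect_equal(nrow(lines), 2)
  expect_equal(lines$base_label[2], "FOLFIRI")
  expect_equal(lines$regimen_label[2], "FOLFIRI+BEV")
  expect_equal(lines$additions[[2]]$drug_id, "bevacizumab")
  expect_equal(lines$additions[[2]]$date, day(128))
})

test_that("the biologic-addition exception is narrow", {
  # (a) inapplicable to adjuvant/first lines: biologic into an adjuvant
  # capecitabine line starts a new line
  rx_adj <- dplyr::bind_rows(
    rx_block("P1", seq(0, 63, 21), "capecitabine"),
    fx_rx("P1", day(40), "bevacizumab"))
  lines_adj <- derive_lines(rx_adj, day(0), data_end = day(400),
                            first_line_number = 0L)
  expect_equal(lines_adj$end_reason[1], "new_drug")
  expect_equal(lines_adj$start_date[2], day(40))

  # (b) biologic + new non-biologic together on a later line -> new line
  rx_mix <- dplyr::bind_rows(
    rx_block("P1", seq(0, 28, 14), c("capecitabine", "bevacizumab")),
    rx_block("P1", seq(100, 128, 14), FOLFIRI),
    rx_block("P1", 150, c("oxaliplatin", "ramucirumab")))
  lines_mix <- derive_lines(rx_mix, day(0), data_end = day(400))
  expect_equal(nrow(lines_mix), 3)
  expect_equal(lines_mix$end_reason[2], "new_drug")

  # (c) a second biologic into a regimen that already has one -> new line
  rx_two <- dplyr::bind_rows(
    rx_block("P1", seq(0, 28, 14), c("capecitabine", "bevacizumab")),
    rx_block("P1", seq(100, 128, 14), c(FOLFIRI, "bevacizumab")),
    fx_rx("P1", day(150), "ramucirumab"))
  lines_two <- derive_lines(rx_two, day(0), data_end = day(400))
  expect_equal(nrow(lines_two), 3)
  expect_equal(lines_two$start_date[3], day(150))
})

test_that("evaluability needs more than 60 days of data; completion 60 or more", {
  lines <- tibble::tibble(end_date = day(c(200, 200)),
                          expected_final_dose_date = day(c(300, 300)))
  # 261 - 200 = 61 > 60 -> evaluable; 260 - 200 = 60 -> not
  s61 <- completion_status(lines[1, ], FALSE, day(261))
  s60 <- completion_status(lines[1, ], FALSE, day(260))
  expect_true(s61$evaluable_for_transition)
  expect_false(s60$evaluable_for_transition)
  # a subsequent line makes the line evaluable regardless of margin
  expect_true(completion_status(lines[1, ], TRUE, day(201))$evaluable_for_transition)
  # completion: 360 - 300 = 60 >= 60 -> completed; 359 - 300 = 59 -> censored
  expect_true(completion_status(lines[1, ], FALSE, day(360))$completed)
  expect_false(completion_status(lines[1, ], FALSE, day(359))$completed)
})

test_that("in-regimen prescriptions never move earlier line boundaries", {
  rx <- dplyr::bind_rows(
    rx_block("P1", seq(0, 84, 14), c(FOLFOX, "bevacizumab")),
    rx_block("P1", seq(200, 242, 14), FOLFIRI))
  base <- derive_lines(rx, day(0), data_end = day(500))
  # insert an extra oxaliplatin claim inside line 1
  rx2 <- dplyr::bind_rows(rx, fx_rx("P1", day(49), "oxaliplatin")) |>
    dplyr::arrange(date)
  more <- derive_lines(rx2, day(0), data_end = day(500))
  expect_equal(more$start_date, base$start_date)
  expect_equal(more$end_date, base$end_date)
  expect_equal(more$end_reason, base$end_reason)
})

test_that("last line ends at min(expected final dose, data_end)", {
  rx <- rx_block("P1", seq(0, 28, 14), c(FOLFOX, "bevacizumab"))
  # expected final dose day 42; plentiful data -> ends at day 42
  l1 <- derive_lines(rx, day(0), data_end = day(300))
  expect_equal(l1$end_date, day(42))
  expect_equal(l1$end_reason, "data_end")
  # data ends day 35 -> censored there
  l2 <- derive_lines(rx, day(0), data_end = day(35))
  expect_equal(l2$end_date, day(35))
  expect_equal(nrow(derive_lines(rx[0, ], day(0), data_end = day(35))), 0)
})
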