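test_that("the first available assessment of each day is selected", {
  a <- tibble::tibble(
    unit_id = c("U1", "U1", "U1", "U2"),
    date = as.Date(c("2017-01-02", "2017-01-02", "2017-01-03", "2017-01-02")),
    assessment_time = c("07:40", "15:10", "15:10", "08:05"),
    n_level0 = 1:4
  )
  sel <- select_daily_assessment(a)
  expect_equal(nrow(sel), 3)
  expect_equal(sel$assessment_time[sel$unit_id == "U1" &
                                     sel$date == "2017-01-02"], "07:40")
  # a day with only a later assessment falls back to it
  expect_equal(sel$assessment_time[sel$date == "2017-01-03"], "15:10")
  # a unit-day with no assessment at all has no row
  expect_false(any(sel$unit_id == "U2" & sel$date == "2017-01-03"))
  # selecting again changes nothing (idempotent)
  expect_identical(select_daily_assessment(sel), sel)
})

test_that("the plus-minus 3 SD rule removes extreme shortfall days per unit", {
  days <- tibble::tibble(
    unit_id = "U1",
    date = as.Date("2017-01-01") + 0:99,
    total_shortfall_hppd = c(rnorm(99, 0, 0.1), 15)
  )
  out <- remove_shortfall_outliers(days)
  expect_equal(nrow(out$removed), 1)
  expect_equal(out$removed$total_shortfall_hppd, 15)
  # partitions are disjoint and exhaustive
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(days))
  expect_equal(dplyr::bind_rows(out$kept, out$removed) |>
                 dplyr::arrange(date), days |> dplyr::arrange(date))
  # second pass on the kept days removes nothing here (idempotent)
  expect_equal(nrow(remove_shortfall_outliers(out$kept)$removed), 0)

  # all-identical series: SD = 0, nothing removed
  same <- tibble::tibble(unit_id = "U2", date = days$date,
                         total_shortfall_hppd = 0.4)
  expect_equal(nrow(remove_shortfall_outliers(same)$removed), 0)
})

test_that("the 3 SD rule removes the expected normal tail mass", {
  n <- 1e5
  days <- tibble::tibble(
    unit_id = "U1", date = seq_len(n),
    total_shortfall_hppd = withr::with_seed(31, rnorm(n))
  )
  out <- remove_shortfall_outliers(days)
  pct <- 100 * nrow(out$removed) / n
  expect_gt(pct, 0.17)  # 2 * pnorm(-3) = 0.27%
  expect_lt(pct, 0.37)
})

test_that("units are split at change events and short segments dropped", {
  days <- tibble::tibble(unit_id = "U1",
                         date = as.Date("2017-01-01") + 0:299, x = 1)
  ev <- tibble::tibble(unit_id = "U1", date = as.Date("2017-06-01"))
  out <- split_units_on_change(days, ev)
  expect_setequal(unique(out$data$unit_id), c("U1/a", "U1/b"))
  expect_equal(nrow(out$data), 300)

  # no events: identity
  out0 <- split_units_on_change(days, NULL)
  expect_identical(out0$data, days)

  # two events -> three segments: reconfigured units count separately,
  # so the analysis fleet can exceed the number of physical units
  ev2 <- tibble::tibble(unit_id = "U1",
                        date = as.Date(c("2017-04-01", "2017-09-01")))
  out2 <- split_units_on_change(days, ev2)
  expect_equal(dplyr::n_distinct(out2$data$unit_id), 3)

  # a segment shorter than min_days is dropped and logged
  ev3 <- tibble::tibble(unit_id = "U1", date = as.Date("2017-10-18"))
  expect_message(out3 <- split_units_on_change(days, ev3, min_days = 28),
                 "dropping")
  expect_setequal(unique(out3$data$unit_id), "U1/a")
  expect_false(out3$segments$kept[out3$segments$derived_id == "U1/b"])
})

test_that("reverse-coded units are flagged by concordant rate reversals", {
  honest <- rep(list(c(0.8, 0.05, 0.05)), 8)
  names(honest) <- sprintf("U%02d", 1:8)
  honest$U09 <- c(0.30, 0.20, 0.20)  # honestly low-adequacy unit
  resp <- make_response_table(honest, n_days = 120, seed = 41)
  contaminated <- inject_reverse_coding(resp, c("U02", "U05"))

  det <- detect_reverse_coding(contaminated)
  expect_setequal(det$unit_id[det$flagged], c("U02", "U05"))
  # the honest low-adequacy unit is NOT flagged (one indicator only)
  expect_false(det$flagged[det$unit_id == "U09"])

  fixed <- detect_and_recode_reverse_coding(contaminated)
  expect_setequal(fixed$flagged_units, c("U02", "U05"))
  # full restoration
  expect_equal(fixed$responses, resp, ignore_attr = TRUE)
  # involution: re-running detection on restored data flags nothing
  redet <- detect_and_recode_reverse_coding(fixed$responses)
  expect_length(redet$flagged_units, 0)
})

test_that("short units are left unflagged with a warning", {
  resp <- make_response_table(list(U1 = c(0.8, 0.05, 0.05),
                                   U2 = c(0.8, 0.05, 0.05)), n_days = 60)
  tiny <- make_response_table(list(U3 = c(0.2, 0.9, 0.9)), n_days = 10)
  expect_warning(det <- detect_reverse_coding(dplyr::bind_rows(resp, tiny)),
                 "unassessed")
  expect_false(det$flagged[det$unit_id == "U3"])
})

test_that("recoding errors on unknown units and inverts exactly", {
  resp <- make_response_table(list(U1 = c(0.8, 0.05, 0.05)), n_days = 40)
  expect_error(recode_reverse_coding(resp, "nope"), "unknown unit")
  twice <- recode_reverse_coding(recode_reverse_coding(resp, "U1"), "U1")
  expect_equal(as.data.frame(twice), as.data.frame(resp))
})

test_that("linkage joins the next morning's response to the staffing day", {
  ms <- default_ms
  dates <- as.Date("2017-05-01") + 0:9
  census <- tibble::tibble(
    unit_id = "U1", date = dates, assessment_time = "07:30",
    n_level0 = 10, n_level1a = 4, n_level1b = 3, n_level2 = 2, n_level3 = 0,
    admin_count_0700 = 19, patient_hours = 19 * 24,
    admissions = 2, discharges = 2, specialing_count = 0
  )
  staffing <- tibble::tibble(unit_id = "U1", date = dates,
                             rn_hours = 80, na_hours = 60)
  profiles <- tibble::tibble(unit_id = "U1", hospital_id = "A",
                             specialty = "surgical", single_room_prop = 0.3)
  responses <- tibble::tibble(
    unit_id = "U1", date = dates + 1, response_time = "07:45",
    enough_staff = 1L, care_left_undone = 0L, breaks_missed = 0L
  )
  responses <- responses[-3, ]  # one missing response day
  orphan <- tibble::tibble(unit_id = "U1", date = as.Date("2019-01-01"),
                           response_time = "07:45", enough_staff = 1L,
                           care_left_undone = 0L, breaks_missed = 0L)
  linked <- link_days(census, staffing, dplyr::bind_rows(responses, orphan),
                      profiles, ms)
  expect_equal(nrow(linked), 10)
  expect_equal(sum(!is.na(linked$enough_staff)), 9)
  expect_true(is.na(linked$enough_staff[linked$date == dates[3]]))
  expect_equal(attr(linked, "n_orphan_responses"), 1)
  expect_equal(linked$surgical, rep(1L, 10))
  # Monday reference day-of-week coding
  expect_equal(levels(linked$day_of_week)[1], "Mon")
  expect_equal(as.character(linked$day_of_week[1]), "Mon")  # 2017-05-01

  # duplicate unit-day keys are refused by name
  dup <- dplyr::bind_rows(census, census[1, ])
  expect_error(link_days(dup, staffing, NULL, profiles, ms),
               "duplicate unit-day")
})
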