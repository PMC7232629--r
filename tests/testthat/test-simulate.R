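test_that("the fleet generator is deterministic and matches its frame", {
  cfg <- fleet_config(seed = 61)
  p1 <- generate_fleet(cfg)
  p2 <- generate_fleet(cfg)
  expect_identical(p1, p2)
  expect_equal(dplyr::n_distinct(p1$hospital_id), 4)
  expect_equal(nrow(p1), 80)
  expect_true(all(p1$beds >= 20 & p1$beds <= 36))
  # ~27 beds/unit: the fleet totals a couple of thousand beds
  expect_gt(sum(p1$beds), 2050)
  expect_lt(sum(p1$beds), 2270)
  expect_true(all(p1$single_room_prop >= 0 & p1$single_room_prop <= 1))
  expect_true(all(p1$planned_skill_mix >= 0.35 & p1$planned_skill_mix <= 0.8))
  expect_false(anyDuplicated(p1$unit_id) > 0)

  tiny <- generate_fleet(fleet_config(n_hospitals = 1,
                                      units_per_hospital = 1, seed = 1))
  expect_equal(nrow(tiny), 1)
  expect_error(fleet_config(units_per_hospital = 0))
})

test_that("unit-days are reproducible, non-negative and calibrated", {
  cfg <- fleet_config(n_hospitals = 2, units_per_hospital = 6, days = 120,
                      seed = 62)
  prof <- generate_fleet(cfg)
  ud1 <- generate_unit_days(prof, seed = 62)
  ud2 <- generate_unit_days(prof, seed = 62)
  expect_identical(ud1$census, ud2$census)
  expect_identical(ud1$staffing, ud2$staffing)

  cen <- ud1$census
  counts <- as.matrix(cen[paste0("n_level", c("0", "1a", "1b", "2", "3"))])
  expect_true(all(counts >= 0))
  expect_true(all(cen$patient_hours >= 0))
  expect_true(all(cen$admin_count_0700 >= 1))
  expect_true(all(ud1$staffing$rn_hours >= 0 & ud1$staffing$na_hours >= 0))
  expect_true(all(rowSums(counts) == cen$admin_count_0700))
  # two assessments per day before any thinning
  expect_equal(nrow(ud1$assessments), 2 * nrow(cen))

  # establishment series land on the planted unit means and CVs
  linked <- link_days(cen, ud1$staffing, NULL, prof)
  per_unit <- linked |>
    dplyr::group_by(unit_id) |>
    dplyr::summarise(m = mean(establishment_wte),
                     cv = sd(establishment_wte) / mean(establishment_wte))
  tr <- ud1$unit_truth
  expect_equal(per_unit$m, tr$mean_multiplier * tr$mean_census,
               tolerance = 0.06)
  expect_equal(mean(per_unit$cv), mean(tr$establishment_cv),
               tolerance = 0.08)
})

test_that("degenerate calibrations collapse the pipeline as expected", {
  cfg <- fleet_config(n_hospitals = 1, units_per_hospital = 3, days = 60,
                      seed = 63)
  prof <- generate_fleet(cfg)
  # zero day-to-day variation: constant establishment, zero-width bootstrap
  cal0 <- calibration_profile(cv_mean = 1e-9, cv_sd = 0,
                              cv_bounds = c(0, 1),
                              shortfall_mean_hppd = 0, shortfall_sd_hppd = 0)
  ud <- generate_unit_days(prof, cal0, seed = 63)
  linked <- link_days(ud$census, ud$staffing, NULL, prof)
  spread <- tapply(linked$establishment_wte, linked$unit_id,
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
  r <- bootstrap_establishment(
    linked$establishment_wte[linked$unit_id == linked$unit_id[1]],
    n_days = 20, n_boot = 200, seed = 1
  )
  expect_identical(r$ci_width, 0)
  expect_identical(r$precision_pct, 0)
  # zero shortfall: deployed equals required, HPPD equals requirement
  expect_equal(linked$total_hppd, linked$requirement_hppd, tolerance = 1e-10)
  expect_equal(linked$total_shortfall_hppd, rep(0, nrow(linked)),
               tolerance = 1e-10)
})

test_that("simulated outcome rates hit the calibrated marginals", {
  fx <- small_linked_study(seed = 64, days = 120)
  linked <- fx$linked
  expect_lt(abs(mean(linked$enough_staff) - 0.78), 0.02)
  expect_lt(abs(mean(linked$care_left_undone) - 0.05), 0.015)
  expect_lt(abs(mean(linked$breaks_missed) - 0.05), 0.015)
  # responses are dated the following morning
  expect_equal(min(as.Date(fx$study$responses$date)),
               min(as.Date(linked$date)) + 1L)
  # determinism of the whole study bundle
  st2 <- simulate_study(
    config = fleet_config(n_hospitals = 4, units_per_hospital = 5,
                          days = 120, seed = 64),
    seed = 64, missingness = NULL
  )
  expect_identical(st2$responses, fx$study$responses)
})

test_that("the realised random-intercept variances equal the planted ones", {
  fx <- small_linked_study(seed = 65, days = 30)
  tr <- fx$study$truth_realized$enough_staff
  truth <- fx$study$truth$enough_staff
  ml_var <- function(x) mean((x - mean(x))^2)
  expect_equal(ml_var(tr$unit_effects), truth$var_unit, tolerance = 1e-9)
  expect_equal(ml_var(tr$hospital_effects), truth$var_hosp, tolerance = 1e-9)
  # unit effects centred within hospital: orthogonal to the hospital level
  units <- fx$study$profiles
  by_hosp <- tapply(tr$unit_effects[units$unit_id], units$hospital_id, mean)
  expect_true(all(abs(by_hosp) < 1e-9))
})

test_that("reverse-coding injection is an involution and checks its units", {
  resp <- make_response_table(list(U1 = c(0.8, 0.05, 0.05),
                                   U2 = c(0.7, 0.1, 0.1)), n_days = 30)
  expect_error(inject_reverse_coding(resp, "UX"), "unknown unit")
  once <- inject_reverse_coding(resp, "U1")
  expect_equal(attr(once, "reverse_coded_units"), "U1")
  expect_equal(once$enough_staff[once$unit_id == "U1"],
               1L - resp$enough_staff[resp$unit_id == "U1"])
  twice <- inject_reverse_coding(once, "U1")
  expect_equal(twice, resp, ignore_attr = TRUE)
  none <- inject_reverse_coding(resp, character())
  expect_equal(none, resp, ignore_attr = TRUE)
})

test_that("missingness injection thins at the configured rates", {
  cfg <- fleet_config(n_hospitals = 2, units_per_hospital = 8, days = 150,
                      seed = 66)
  prof <- generate_fleet(cfg)
  ud <- generate_unit_days(prof, seed = 66)
  resp <- make_response_table(
    stats::setNames(rep(list(c(0.8, 0.05, 0.05)), nrow(prof)),
                    prof$unit_id),
    n_days = 150
  )
  th <- inject_missingness(ud$assessments, resp, 0.04, 0.15, seed = 66)
  # only morning rows are removed, at ~4%
  n_morning <- sum(ud$assessments$assessment_time < "12:00")
  kept_morning <- sum(th$assessments$assessment_time < "12:00")
  expect_equal(kept_morning / n_morning, 0.96, tolerance = 0.015)
  expect_equal(sum(th$assessments$assessment_time >= "12:00"),
               sum(ud$assessments$assessment_time >= "12:00"))
  expect_equal(nrow(th$responses) / nrow(resp), 0.85, tolerance = 0.02)
  # every unit-day still has at least the afternoon rating available
  sel <- select_daily_assessment(th$assessments)
  expect_equal(nrow(sel), nrow(ud$census))

  id <- inject_missingness(ud$assessments, resp, 0, 0, seed = 1)
  expect_identical(id$assessments, ud$assessments)
  expect_identical(id$responses, resp)
  gone <- inject_missingness(ud$assessments, resp, 0, 1, seed = 1)
  expect_equal(nrow(gone$responses), 0)
})

test_that("derived seeds stay within 32-bit integer range", {
  for (s in c(1, 2, 1000, 123456789, 2^30)) {
    for (k in 0:6) {
      d <- derive_seed(s, k)
      expect_true(is.integer(d) || (is.finite(d) && abs(d) < 2^31))
    }
  }
  expect_identical(derive_seed(42, 3), derive_seed(42, 3))
  expect_false(derive_seed(42, 3) == derive_seed(42, 4))
})
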