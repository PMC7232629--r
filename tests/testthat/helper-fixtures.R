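# Shared fixtures: all synthetic, generated in code at test time.

default_ms <- multiplier_set()

# Brute-force workload oracle: per-patient summation and an independent
# re-implementation of the uplift/week conversion.
oracle_weighted_multiplier <- function(counts, ms) {
  per_patient <- rep(unname(ms$multipliers), times = counts)
  mean(per_patient)
}

oracle_daily_hours <- function(establishment, ms) {
  weekly_hours_without_uplift <-
    establishment * ms$wte_weekly_hours / (1 + ms$uplift_fraction)
  weekly_hours_without_uplift / 7
}

random_census <- function(ms, max_count = 30) {
  counts <- stats::rpois(length(ms$levels), lambda = 4)
  if (sum(counts) == 0) counts[1] <- 1
  stats::setNames(counts, ms$levels)
}

# A small complete-data synthetic study with outcomes attached to the
# linked table (no missingness, no contamination).
small_linked_study <- function(seed, n_hospitals = 4, units_per_hospital = 5,
                               days = 120, truth = adequacy_truth(),
                               calibration = calibration_profile()) {
  study <- simulate_study(
    config = fleet_config(n_hospitals = n_hospitals,
                          units_per_hospital = units_per_hospital,
                          days = days, seed = seed),
    calibration = calibration, truth = truth,
    seed = seed, missingness = NULL
  )
  linked <- attach_outcomes(study$linked_truth, study$responses)
  list(study = study, linked = linked)
}

attach_outcomes <- function(linked, responses) {
  resp <- responses
  resp$date <- as.Date(resp$date) - 1L
  dplyr::left_join(
    linked,
    resp[c("unit_id", "date", "enough_staff", "care_left_undone",
           "breaks_missed")],
    by = c("unit_id", "date")
  )
}

# Bernoulli response table for reverse-coding tests: units with given
# marginal rates for the three answers.
make_response_table <- function(unit_rates, n_days = 120, seed = 1,
                                start = as.Date("2017-01-02")) {
  withr::with_seed(seed, {
    rows <- lapply(names(unit_rates), function(u) {
      r <- unit_rates[[u]]
      tibble::tibble(
        unit_id = u,
        date = start + seq_len(n_days) - 1L,
        response_time = "07:30",
        enough_staff = stats::rbinom(n_days, 1, r[1]),
        care_left_undone = stats::rbinom(n_days, 1, r[2]),
        breaks_missed = stats::rbinom(n_days, 1, r[3])
      )
    })
    dplyr::bind_rows(rows)
  })
}
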