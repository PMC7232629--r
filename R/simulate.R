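#' Configuration of a synthetic hospital fleet
#'
#' Describes the study frame the generator emulates: four acute
#' hospitals with roughly twenty general medical/surgical units each,
#' observed daily for a year.  Bed counts are drawn as
#' `20 + Binomial(16, 7/16)` (range 20-36, mean 27), so that at the
#' default occupancy of 0.79 the fleet-mean daily census is about 21.3
#' patients.  About a third of units are surgical; the single-room
#' proportion is Beta-distributed; the planned skill mix (registered
#' nurse share of care hours) is Normal around 0.56, clamped to
#' `[0.35, 0.80]`.
#'
#' @param n_hospitals Number of hospitals.
#' @param units_per_hospital Units per hospital; a scalar or one value
#'   per hospital (e.g. `c(22, 22, 21, 21)` for an 86-unit fleet).
#' @param days Days observed per unit.
#' @param occupancy Mean occupied fraction of beds.
#' @param prop_surgical Fraction of surgical units.
#' @param single_room_shape Two Beta shape parameters for the
#'   single-room proportion.
#' @param skill_mix_mean,skill_mix_sd Planned skill-mix distribution.
#' @param start_date First study day (ISO date).
#' @param seed Optional integer seed.
#' @return A list of class `fleet_config`.
#' @export
fleet_config <- function(n_hospitals = 4, units_per_hospital = 20,
                         days = 365, occupancy = 0.79,
                         prop_surgical = 0.35,
                         single_room_shape = c(2, 4),
                         skill_mix_mean = 0.56, skill_mix_sd = 0.08,
                         start_date = "2017-01-01", seed = NULL) {
  stopifnot(n_hospitals >= 1, all(units_per_hospital >= 1), days >= 1,
            occupancy > 0, occupancy <= 1,
            prop_surgical >= 0, prop_surgical <= 1,
            skill_mix_mean > 0, skill_mix_mean < 1)
  structure(
    list(n_hospitals = n_hospitals,
         units_per_hospital = units_per_hospital, days = days,
         occupancy = occupancy, prop_surgical = prop_surgical,
         single_room_shape = single_room_shape,
         skill_mix_mean = skill_mix_mean, skill_mix_sd = skill_mix_sd,
         start_date = as.Date(start_date), seed = seed),
    class = "fleet_config"
  )
}

#' Calibration of the synthetic unit-day process
#'
#' Sets the scale of the generated workload so the pipeline's outputs
#' land on realistic values: a fleet-mean weighted multiplier of 1.64
#' (which at a 22% uplift and 37.5-hour week implies a care requirement
#' of about 7.2 hours per patient day, and with a mean census of ~21.3
#' a mean establishment of ~35 WTE); a per-unit coefficient of
#' variation of the daily establishment drawn from a Gamma distribution
#' with mean 9.4% (so a 20-day audit has a mean precision of about 4%);
#' daily total staffing shortfalls Normal with mean 0.1 and SD 0.9 HPPD
#' split between registered nurses and assistants by the unit's skill
#' mix; specialing patients Poisson(0.15) per unit-day; and patient
#' flows scaled so turnover is about 0.04 patients per staff hour.
#'
#' @param mean_multiplier Fleet-mean weighted acuity multiplier.
#' @param multiplier_sd_between Between-unit SD of the unit-mean
#'   multiplier.
#' @param multiplier_bounds Clamp for unit-mean multipliers.
#' @param cv_mean,cv_sd Mean and SD of the Gamma distribution of the
#'   per-unit establishment coefficient of variation.
#' @param cv_bounds Clamp for unit CVs.
#' @param census_cv_share Share of the establishment variance carried
#'   by day-to-day census-size variation (the rest is case-mix).
#' @param shortfall_mean_hppd,shortfall_sd_hppd Daily total-shortfall
#'   distribution in hours per patient day.
#' @param shortfall_cor Correlation between the registered-nurse and
#'   assistant shortfall draws (default 0: independent rosters;
#'   positive values let the two groups be short-staffed together,
#'   which makes the two shortfall terms confounded).
#' @param specialing_rate Poisson rate of one-to-one patients per
#'   unit-day.
#' @param admission_rate,discharge_rate Poisson rates of daily patient
#'   flows.
#' @return A list of class `calibration_profile`.
#' @export
calibration_profile <- function(mean_multiplier = 1.64,
                                multiplier_sd_between = 0.12,
                                multiplier_bounds = c(1.2, 2.4),
                                cv_mean = 0.094, cv_sd = 0.045,
                                cv_bounds = c(0.01, 0.30),
                                census_cv_share = 0.36,
                                shortfall_mean_hppd = 0.1,
                                shortfall_sd_hppd = 0.9,
                                shortfall_cor = 0,
                                specialing_rate = 0.15,
                                admission_rate = 3.1,
                                discharge_rate = 3.1) {
  stopifnot(mean_multiplier > 0, cv_mean > 0, cv_sd >= 0,
            census_cv_share >= 0, census_cv_share <= 1,
            shortfall_sd_hppd >= 0, abs(shortfall_cor) < 1,
            specialing_rate >= 0)
  structure(
    list(mean_multiplier = mean_multiplier,
         multiplier_sd_between = multiplier_sd_between,
         multiplier_bounds = multiplier_bounds,
         cv_mean = cv_mean, cv_sd = cv_sd, cv_bounds = cv_bounds,
         census_cv_share = census_cv_share,
         shortfall_mean_hppd = shortfall_mean_hppd,
         shortfall_sd_hppd = shortfall_sd_hppd,
         shortfall_cor = shortfall_cor,
         specialing_rate = specialing_rate,
         admission_rate = admission_rate,
         discharge_rate = discharge_rate),
    class = "calibration_profile"
  )
}

#' Generate the unit profile table of a synthetic fleet
#'
#' Draws the fixed attributes of every unit once: hospital, bed count,
#' specialty, single-room proportion and planned skill mix.  Unit ids
#' are `"<hospital><nn>"` and unique fleet-wide.
#'
#' @param config A [fleet_config()].
#' @return A tibble with one row per unit (`hospital_id`, `unit_id`,
#'   `beds`, `mean_census`, `specialty`, `single_room_prop`,
#'   `planned_skill_mix`), with `config` attached as an attribute.
#' @export
generate_fleet <- function(config = fleet_config()) {
  stopifnot(inherits(config, "fleet_config"))
  if (!is.null(config$seed)) withr::local_seed(derive_seed(config$seed, 1L))
  uph <- rep_len(config$units_per_hospital, config$n_hospitals)
  n_units <- sum(uph)
  if (n_units < 1) stop("fleet must contain at least one unit", call. = FALSE)
  hospital_id <- rep(LETTERS[seq_len(config$n_hospitals)], times = uph)
  unit_id <- paste0(hospital_id,
                    sprintf("%02d", unlist(lapply(uph, seq_len))))
  beds <- 20L + stats::rbinom(n_units, 16L, 7 / 16)
  specialty <- ifelse(
    stats::runif(n_units) < config$prop_surgical, "surgical",
    sample(c("medical", "mixed"), n_units, replace = TRUE)
  )
  single_room_prop <- stats::rbeta(n_units, config$single_room_shape[1],
                                   config$single_room_shape[2])
  skill <- pmin(pmax(stats::rnorm(n_units, config$skill_mix_mean,
                                  config$skill_mix_sd), 0.35), 0.80)
  profiles <- tibble::tibble(
    hospital_id = hospital_id, unit_id = unit_id, beds = beds,
    mean_census = beds * config$occupancy, specialty = specialty,
    single_room_prop = single_room_prop, planned_skill_mix = skill
  )
  attr(profiles, "config") <- config
  profiles
}

# Interpolated level composition with a given weighted multiplier.
# p_lo is concentrated on low-dependency levels, p_hi tilted towards
# high dependency; any multiplier between the two anchor means is
# reachable by linear interpolation.
composition_anchors <- function(ms) {
  n <- length(ms$multipliers)
  p_lo <- 0.3^(seq_len(n) - 1)
  p_lo <- p_lo / sum(p_lo)
  p_hi <- seq_len(n)
  p_hi <- p_hi / sum(p_hi)
  list(p_lo = p_lo, p_hi = p_hi,
       wm_lo = sum(p_lo * ms$multipliers),
       wm_hi = sum(p_hi * ms$multipliers))
}

# Largest-remainder rounding of n * p to integer counts summing to n.
round_composition <- function(n, p) {
  raw <- n * p
  counts <- floor(raw)
  short <- round(n - sum(counts))
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  counts
}

# Greedy single-patient moves between levels so the integer census hits
# the day's target weighted multiplier as closely as the multiplier grid
# allows; keeps the realised establishment CV equal to the planted one
# instead of inflating it with rounding noise.
refine_composition <- function(counts, multipliers, target_sum) {
  err <- sum(counts * multipliers) - target_sum
  n_lev <- length(multipliers)
  delta <- outer(multipliers, multipliers, function(a, b) b - a)  # i -> j
  for (it in 1:4) {
    cand <- abs(err + delta)
    cand[counts == 0, ] <- Inf
    diag(cand) <- Inf
    best <- arrayInd(which.min(cand), dim(cand))
    if (cand[best] >= abs(err) - 1e-12) break
    counts[best[1]] <- counts[best[1]] - 1
    counts[best[2]] <- counts[best[2]] + 1
    err <- err + delta[best[1], best[2]]
  }
  counts
}

#' Generate a year of unit-day censuses and rosters
#'
#' For each unit, draws a unit-mean multiplier and an establishment
#' coefficient of variation from the calibration profile, then
#' generates per day: a census size (lognormal around the unit mean,
#' clamped to the bed count), a target acuity mix whose weighted
#' multiplier follows the remaining share of the variance, integer
#' level counts matching that mix (largest-remainder rounding), patient
#' flows, specialing patients, and a roster in which deployed hours
#' equal the day's requirement (including specialing) minus a Normal
#' shortfall draw.  Hours are floored at zero; shift leaders assess
#' twice a day (morning and mid-afternoon).
#'
#' @param profiles Output of [generate_fleet()].
#' @param calibration A [calibration_profile()].
#' @param ms An [multiplier_set()].
#' @param seed Optional integer seed.
#' @return A list with `assessments` (two timestamped census rows per
#'   unit-day), `census` (the morning rows only), `staffing`
#'   (`unit_id`, `date`, `rn_hours`, `na_hours`) and `unit_truth` (the
#'   per-unit latent calibration draws, for self-verifying tests).
#' @export
generate_unit_days <- function(profiles, calibration = calibration_profile(),
                               ms = multiplier_set(), seed = NULL) {
  stopifnot(inherits(calibration, "calibration_profile"))
  config <- attr(profiles, "config") %||% fleet_config()
  if (!is.null(seed)) withr::local_seed(derive_seed(seed, 2L))
  anchors <- composition_anchors(ms)
  dates <- config$start_date + seq_len(config$days) - 1L
  n_days <- config$days
  cal <- calibration

  cv_shape <- (cal$cv_mean / max(cal$cv_sd, 1e-9))^2
  cv_rate <- cv_shape / cal$cv_mean

  unit_rows <- vector("list", nrow(profiles))
  staff_rows <- vector("list", nrow(profiles))
  truth_rows <- vector("list", nrow(profiles))
  count_names <- paste0("n_level", gsub("[^0-9a-z]", "", tolower(ms$levels)))

  for (i in seq_len(nrow(profiles))) {
    u <- profiles[i, ]
    m_u <- pmin(pmax(stats::rnorm(1, cal$mean_multiplier,
                                  cal$multiplier_sd_between),
                     cal$multiplier_bounds[1]), cal$multiplier_bounds[2])
    c_u <- if (cal$cv_sd > 0) {
      pmin(pmax(stats::rgamma(1, cv_shape, cv_rate),
                cal$cv_bounds[1]), cal$cv_bounds[2])
    } else {
      cal$cv_mean
    }
    # integer rounding of the census adds variance ~1/12; shrink the
    # lognormal so the realised census CV matches the planted share
    sd_n <- sqrt(max(c_u^2 * cal$census_cv_share -
                       1 / (12 * u$mean_census^2), 0))
    sd_m <- c_u * sqrt(1 - cal$census_cv_share)

    draw_census <- function() {
      n_t <- pmin(pmax(round(u$mean_census *
                               exp(stats::rnorm(n_days, -sd_n^2 / 2, sd_n))),
                       1), u$beds)
      m_t <- pmin(pmax(m_u * exp(stats::rnorm(n_days, -sd_m^2 / 2, sd_m)),
                       anchors$wm_lo), anchors$wm_hi)
      lambda <- (m_t - anchors$wm_lo) / (anchors$wm_hi - anchors$wm_lo)
      p <- outer(1 - lambda, anchors$p_lo) + outer(lambda, anchors$p_hi)
      counts <- t(vapply(seq_len(n_days), function(d) {
        refine_composition(round_composition(n_t[d], p[d, ]),
                           ms$multipliers, n_t[d] * m_t[d])
      }, numeric(length(ms$levels))))
      list(n = n_t, counts = counts)
    }
    morning <- draw_census()
    afternoon <- draw_census()
    afternoon$n <- morning$n  # the 07:00 administrative count is shared

    admissions <- stats::rpois(n_days, cal$admission_rate)
    discharges <- stats::rpois(n_days, cal$discharge_rate)
    specialing <- stats::rpois(n_days, cal$specialing_rate)
    patient_hours <- 24 * morning$n

    wm_morning <- as.vector(morning$counts %*% ms$multipliers) / morning$n
    req_total <- establishment_to_daily_hours(wm_morning * morning$n, ms) +
      specialing * ms$specialing_hours_per_patient_day
    mix <- u$planned_skill_mix
    rho <- cal$shortfall_cor %||% 0
    z1 <- stats::rnorm(n_days)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_days)
    s_rn <- cal$shortfall_mean_hppd * mix +
      cal$shortfall_sd_hppd * sqrt(mix) * z1
    s_na <- cal$shortfall_mean_hppd * (1 - mix) +
      cal$shortfall_sd_hppd * sqrt(1 - mix) * z2
    rn_hours <- pmax(req_total * mix - s_rn * morning$n, 0)
    na_hours <- pmax(req_total * (1 - mix) - s_na * morning$n, 0)

    mk_rows <- function(cen, time_min) {
      minute <- sprintf("%02d:%02d", time_min %/% 60,
                        sample.int(50, n_days, replace = TRUE) + 4)
      out <- tibble::tibble(
        unit_id = u$unit_id, date = dates, assessment_time = minute,
        admin_count_0700 = morning$n, patient_hours = patient_hours,
        admissions = admissions, discharges = discharges,
        specialing_count = specialing
      )
      cnt <- tibble::as_tibble(as.data.frame(cen$counts))
      names(cnt) <- count_names
      dplyr::bind_cols(out[1:3], cnt, out[4:8])
    }
    unit_rows[[i]] <- dplyr::bind_rows(mk_rows(morning, 7 * 60),
                                       mk_rows(afternoon, 15 * 60))
    staff_rows[[i]] <- tibble::tibble(
      unit_id = u$unit_id, date = dates,
      rn_hours = rn_hours, na_hours = na_hours
    )
    truth_rows[[i]] <- tibble::tibble(
      unit_id = u$unit_id, mean_multiplier = m_u, establishment_cv = c_u,
      mean_census = u$mean_census, planned_skill_mix = mix
    )
  }

  assessments <- dplyr::arrange(dplyr::bind_rows(unit_rows),
                                .data$unit_id, .data$date,
                                .data$assessment_time)
  census <- assessments |>
    dplyr::group_by(.data$unit_id, .data$date) |>
    dplyr::slice_min(.data$assessment_time, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  list(
    assessments = assessments,
    census = census,
    staffing = dplyr::bind_rows(staff_rows),
    unit_truth = dplyr::bind_rows(truth_rows)
  )
}

#' Planted effect sizes for the adequacy outcomes
#'
#' The generator's default truth: per-outcome log odds ratios for the
#' staffing and unit covariates, day-of-week effects, random-intercept
#' variances derived from target variance partition coefficients via
#' [vpc_to_variances()], and the marginal yes-rate each outcome is
#' calibrated to (the intercept is solved numerically against the
#' realised covariates and random effects).  Defaults plant odds ratios
#' of 0.89 (registered-nurse shortfall) and 0.86 (assistant shortfall)
#' on the enough-staff outcome, 1.14/1.14 on care left undone and
#' 1.12/1.11 on breaks missed, with marginal rates 0.78, 0.05 and 0.05.
#'
#' @param outcome `NULL` for the list of all three truths, or one
#'   outcome name.
#' @return A named list of truth objects (or a single one), each with
#'   elements `target_rate`, `beta` (named vector: shortfalls,
#'   turnover, surgical, single_room_prop, and `dowTue` ... `dowSun`),
#'   `var_unit`, `var_hosp`, and optional `threshold_at` /
#'   `interactions`.
#' @export
adequacy_truth <- function(outcome = NULL) {
  dow_names <- paste0("dow", c("Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
  mk <- function(rate, rn, na, turn, surg, single, dow, vpc_u, vpc_h) {
    v <- vpc_to_variances(vpc_u, vpc_h)
    list(
      target_rate = rate,
      beta = c(rn_shortfall_hppd = log(rn), na_shortfall_hppd = log(na),
               turnover = log(turn), surgical = log(surg),
               single_room_prop = log(single),
               stats::setNames(log(dow), dow_names)),
      var_unit = unname(v["var_unit"]), var_hosp = unname(v["var_hosp"]),
      threshold_at = NULL, interactions = NULL
    )
  }
  truth <- list(
    enough_staff = mk(0.78, 0.89, 0.86, 0.91, 0.54, 0.54,
                      c(1.12, 1.28, 1.08, 1.03, 1.29, 1.02), 0.22, 0.12),
    care_left_undone = mk(0.05, 1.14, 1.14, 3.36, 2.13, 3.01,
                          c(0.86, 0.96, 0.91, 0.93, 0.75, 1.11), 0.22, 0.17),
    breaks_missed = mk(0.05, 1.12, 1.11, 4.94, 2.15, 2.06,
                       c(0.71, 0.61, 0.81, 0.79, 0.50, 0.82), 0.23, 0.11)
  )
  if (is.null(outcome)) truth else truth[[match.arg(outcome, names(truth))]]
}

#' Simulate next-morning staffing-adequacy responses
#'
#' Draws the three daily yes/no adequacy answers from the planted
#' three-level logistic model: for each outcome, hospital and unit
#' intercepts are drawn Normal and then centred and rescaled so the
#' realised between-group variances equal the planted ones exactly
#' (unit effects are centred within hospital so the two levels stay
#' orthogonal); the linear predictor adds the planted coefficients
#' times the day's covariates; the intercept is solved numerically so
#' the realised mean response probability equals the target marginal
#' rate; answers are Bernoulli draws, independent across outcomes given
#' the linear predictor.  Responses are dated the following morning,
#' which is when the shift leader reports on the preceding 24 hours.
#'
#' @param covariate_days Linked unit-day table (see [link_days()]) with
#'   the covariate columns named in the truth objects plus `unit_id`,
#'   `hospital_id`, `date`, `day_of_week`.
#' @param truth Output of [adequacy_truth()] (all three outcomes).
#' @param seed Optional integer seed.
#' @return A tibble `unit_id`, `date` (assessment morning),
#'   `response_time`, `enough_staff`, `care_left_undone`,
#'   `breaks_missed`, with the realised intercepts and random effects
#'   attached as attribute `"truth_realized"`.
#' @export
simulate_adequacy <- function(covariate_days, truth = adequacy_truth(),
                              seed = NULL) {
  if (!is.null(seed)) withr::local_seed(derive_seed(seed, 3L))
  dat <- covariate_days
  units <- dat |>
    dplyr::distinct(.data$unit_id, .data$hospital_id)
  hosps <- unique(units$hospital_id)

  dow_mat <- stats::model.matrix(~ day_of_week, dat)[, -1, drop = FALSE]
  colnames(dow_mat) <- sub("day_of_week", "dow", colnames(dow_mat))

  out <- tibble::tibble(
    unit_id = dat$unit_id, date = as.Date(dat$date) + 1L,
    response_time = sprintf("07:%02d",
                            sample.int(55, nrow(dat), replace = TRUE) + 4)
  )
  realized <- list()
  for (oc in names(truth)) {
    tr <- truth[[oc]]
    h_eff <- scale_to_variance(stats::rnorm(length(hosps)), tr$var_hosp)
    names(h_eff) <- hosps
    u_raw <- stats::rnorm(nrow(units))
    # centre within hospital, then rescale so realised variance is exact
    u_centred <- stats::ave(u_raw, units$hospital_id,
                            FUN = function(x) x - mean(x))
    u_eff <- scale_to_variance(u_centred, tr$var_unit)
    names(u_eff) <- units$unit_id

    eta <- u_eff[dat$unit_id] + h_eff[dat$hospital_id]
    for (term in names(tr$beta)) {
      x <- if (startsWith(term, "dow")) dow_mat[, term] else dat[[term]]
      if (!is.null(tr$threshold_at) &&
          term %in% c("rn_shortfall_hppd", "na_shortfall_hppd")) {
        x <- pmax(x - tr$threshold_at, 0)
      }
      eta <- eta + tr$beta[[term]] * x
    }
    for (ia in tr$interactions %||% list()) {
      eta <- eta + ia$beta * dat[[ia$terms[1]]] * dat[[ia$terms[2]]]
    }
    alpha <- stats::uniroot(
      function(a) mean(stats::plogis(a + eta)) - tr$target_rate,
      interval = c(-20, 20), tol = 1e-10
    )$root
    out[[oc]] <- stats::rbinom(nrow(dat), 1L, stats::plogis(alpha + eta))
    realized[[oc]] <- list(intercept = alpha, unit_effects = u_eff,
                           hospital_effects = h_eff)
  }
  attr(out, "truth_realized") <- realized
  out
}

scale_to_variance <- function(x, target_var) {
  if (length(x) < 2 || target_var <= 0) return(rep(0, length(x)))
  x <- x - mean(x)
  v <- mean(x^2)  # maximum-likelihood (divisor n) variance, as glmer reports
  if (v == 0) return(rep(0, length(x)))
  x * sqrt(target_var / v)
}

#' Contaminate responses with consistent reverse coding
#'
#' Inverts all three 0/1 adequacy answers for the listed units,
#' emulating units whose staff were trained to enter the coding the
#' wrong way round.  Applying it twice restores the original data.
#'
#' @param responses Response table.
#' @param unit_ids Units to invert; unknown ids are an error.
#' @return The contaminated table, with the injected unit ids recorded
#'   in attribute `"reverse_coded_units"` for round-trip tests.
#' @export
inject_reverse_coding <- function(responses, unit_ids) {
  out <- recode_reverse_coding(responses, unit_ids)
  attr(out, "reverse_coded_units") <- unit_ids
  out
}

#' Thin assessments and responses to emulate missing data
#'
#' Removes *morning* assessments at rate `r_assessment` (the afternoon
#' assessment of the same day survives, exercising the
#' first-available-rating fallback) and whole response records at rate
#' `r_response`.  Defaults reproduce usable ratings on ~96% of
#' unit-days and responses on ~85%.
#'
#' @param assessments Assessment table (two rows per unit-day).
#' @param responses Response table.
#' @param r_assessment,r_response Removal rates in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return `list(assessments, responses)`.
#' @export
inject_missingness <- function(assessments, responses,
                               r_assessment = 0.04, r_response = 0.15,
                               seed = NULL) {
  stopifnot(r_assessment >= 0, r_assessment <= 1,
            r_response >= 0, r_response <= 1)
  if (!is.null(seed)) withr::local_seed(derive_seed(seed, 4L))
  is_morning <- assessments$assessment_time < "12:00"
  drop_a <- is_morning &
    stats::runif(nrow(assessments)) < r_assessment
  drop_r <- stats::runif(nrow(responses)) < r_response
  list(assessments = assessments[!drop_a, , drop = FALSE],
       responses = responses[!drop_r, , drop = FALSE])
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running the whole generator: fleet profiles,
#' a year of censuses and rosters, linked covariates, adequacy
#' responses from the planted truth, then (optionally) missingness and
#' reverse-coding contamination.
#'
#' @param config A [fleet_config()].
#' @param calibration A [calibration_profile()].
#' @param truth Output of [adequacy_truth()].
#' @param ms An [multiplier_set()].
#' @param seed Master seed for all stages.
#' @param missingness `NULL` for none, or a list with `r_assessment`
#'   and `r_response`.
#' @param reverse_coded_units Unit ids to contaminate, or `NULL`.
#' @return A list: `profiles`, `assessments`, `staffing`, `responses`,
#'   `linked_truth` (the uncontaminated covariate table the outcomes
#'   were simulated from), `unit_truth`, `truth`, `truth_realized`.
#' @export
simulate_study <- function(config = fleet_config(),
                           calibration = calibration_profile(),
                           truth = adequacy_truth(),
                           ms = multiplier_set(), seed = NULL,
                           missingness = list(r_assessment = 0.04,
                                              r_response = 0.15),
                           reverse_coded_units = NULL) {
  if (is.null(config$seed) && !is.null(seed)) config$seed <- seed
  profiles <- generate_fleet(config)
  ud <- generate_unit_days(profiles, calibration, ms, seed = seed)
  linked0 <- link_days(ud$census, ud$staffing, responses = NULL,
                       profiles = profiles, ms = ms)
  responses <- simulate_adequacy(linked0, truth, seed = seed)
  truth_realized <- attr(responses, "truth_realized")
  assessments <- ud$assessments
  if (!is.null(missingness)) {
    thinned <- inject_missingness(assessments, responses,
                                  missingness$r_assessment %||% 0.04,
                                  missingness$r_response %||% 0.15,
                                  seed = seed)
    assessments <- thinned$assessments
    responses <- thinned$responses
  }
  if (!is.null(reverse_coded_units)) {
    responses <- inject_reverse_coding(responses, reverse_coded_units)
  }
  list(profiles = profiles, assessments = assessments,
       staffing = ud$staffing, responses = responses,
       linked_truth = linked0, unit_truth = ud$unit_truth,
       truth = truth, truth_realized = truth_realized)
}
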