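#' Weighted average staffing multiplier for one census
#'
#' The daily acuity census assigns each patient to one SNCT level; the
#' weighted average multiplier is the census-weighted mean of the level
#' multipliers, \eqn{\sum_l n_l m_l / \sum_l n_l}.  It is bounded by the
#' smallest and largest multiplier.
#'
#' @param counts Numeric vector of patients per level.  If named, names
#'   are matched against `ms$levels`; otherwise positions are used and
#'   the length must equal the number of levels.
#' @param ms An [multiplier_set()] object.
#' @return The dimensionless mean multiplier.
#' @examples
#' weighted_multiplier(c("0" = 10, "1a" = 5, "1b" = 3, "2" = 2, "3" = 0),
#'                     multiplier_set())
#' @export
weighted_multiplier <- function(counts, ms = multiplier_set()) {
  counts <- check_census_counts(counts, ms)
  total <- sum(counts)
  if (total <= 0) {
    stop("empty census: all level counts are zero, no multiplier is defined",
         call. = FALSE)
  }
  sum(counts * ms$multipliers) / total
}

check_census_counts <- function(counts, ms) {
  counts <- unlist(counts)
  if (!is.null(names(counts))) {
    unknown <- setdiff(names(counts), ms$levels)
    if (length(unknown) > 0) {
      stop("unknown acuity levels: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    full <- stats::setNames(numeric(length(ms$levels)), ms$levels)
    full[names(counts)] <- counts
    counts <- full
  } else if (length(counts) != length(ms$levels)) {
    stop("`counts` must have one entry per level (", length(ms$levels), ")",
         call. = FALSE)
  } else {
    counts <- stats::setNames(as.numeric(counts), ms$levels)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("census counts must be finite and >= 0", call. = FALSE)
  }
  counts
}

#' Estimated establishment (WTE) for one unit-day
#'
#' Multiplies the weighted average multiplier from the shift-leader
#' census by the patient count drawn from the patient administration
#' system (deliberately, in case patients were omitted from the shift
#' leader's report).  The result estimates the number of staff the unit
#' needs to employ, including the uplift for leave and sickness.
#'
#' @inheritParams weighted_multiplier
#' @param admin_count Patient count at 07:00 from the administration
#'   system; may differ from `sum(counts)`.
#' @return Establishment in WTE; zero when `admin_count` is zero.
#' @export
establishment_wte <- function(counts, admin_count, ms = multiplier_set()) {
  stopifnot(is.numeric(admin_count), length(admin_count) == 1L,
            is.finite(admin_count))
  if (admin_count < 0) stop("`admin_count` must be >= 0", call. = FALSE)
  if (admin_count == 0) return(0)
  weighted_multiplier(counts, ms) * admin_count
}

#' Convert an establishment to implied daily care hours (and back)
#'
#' An establishment is a number of staff employed (WTE) including the
#' uplift for annual leave, study time and sickness.  The daily hours of
#' care it can supply are obtained by removing the uplift (dividing by
#' 1 + uplift) and converting WTE-weeks to hours per day:
#' \deqn{h = E / (1 + u) \times W / 7.}
#' `daily_hours_to_establishment()` is the exact inverse.
#'
#' @param establishment Establishment in WTE (>= 0).
#' @param hours Daily care hours (>= 0).
#' @inheritParams weighted_multiplier
#' @return Care hours per day, or WTE for the inverse.
#' @export
establishment_to_daily_hours <- function(establishment, ms = multiplier_set()) {
  stopifnot(is.numeric(establishment), all(is.finite(establishment)))
  if (any(establishment < 0)) {
    stop("`establishment` must be >= 0", call. = FALSE)
  }
  establishment / (1 + ms$uplift_fraction) * ms$wte_weekly_hours / 7
}

#' @rdname establishment_to_daily_hours
#' @export
daily_hours_to_establishment <- function(hours, ms = multiplier_set()) {
  stopifnot(is.numeric(hours), all(is.finite(hours)))
  if (any(hours < 0)) stop("`hours` must be >= 0", call. = FALSE)
  hours * 7 / ms$wte_weekly_hours * (1 + ms$uplift_fraction)
}

#' Required daily care hours for one unit-day
#'
#' Converts the census-implied establishment into daily hours and, when
#' `include_specialing = TRUE`, adds the hours implied by one-to-one
#' supervised patients.  Specialing is included when computing the
#' requirement for a particular day (and hence shortfalls), but *not*
#' when estimating establishments to employ, because the multipliers
#' already average over enhanced care.
#'
#' @inheritParams establishment_wte
#' @param specialing_count Number of patients under one-to-one
#'   supervision that day.
#' @param include_specialing Add specialing hours?  Off for
#'   establishment estimation, on for daily shortfalls.
#' @return Care hours per day.
#' @export
required_hours <- function(counts, admin_count, specialing_count = 0,
                           ms = multiplier_set(), include_specialing = FALSE) {
  stopifnot(is.numeric(specialing_count), specialing_count >= 0)
  base <- establishment_to_daily_hours(
    establishment_wte(counts, admin_count, ms), ms
  )
  if (include_specialing) {
    base <- base + specialing_count * ms$specialing_hours_per_patient_day
  }
  base
}

#' Split care hours between registered nurses and assistants
#'
#' The planned skill mix is the proportion of care hours delivered by
#' registered nurses; the unit's average observed skill mix is used as a
#' proxy for it.
#'
#' @param hours Total care hours (>= 0), vectorised.
#' @param skill_mix Proportion registered-nurse, in `[0, 1]`.
#' @return Named list with components `rn` and `na`; `rn + na == hours`
#'   exactly.
#' @export
split_by_skill_mix <- function(hours, skill_mix) {
  stopifnot(is.numeric(hours), is.numeric(skill_mix))
  if (any(!is.finite(skill_mix)) || any(skill_mix < 0) || any(skill_mix > 1)) {
    stop("`skill_mix` must lie in [0, 1]", call. = FALSE)
  }
  if (any(hours < 0)) stop("`hours` must be >= 0", call. = FALSE)
  rn <- hours * skill_mix
  list(rn = rn, na = hours - rn)
}

#' Hours per patient-day (HPPD)
#'
#' Staff hours divided by patient-days, where one patient-day is 24
#' occupied-bed hours.
#'
#' @param staff_hours Care hours in the 24-hour window (vectorised).
#' @param patient_hours Occupied-bed hours in the same window; must be
#'   strictly positive (a day with zero patient-hours has no defined
#'   HPPD and is excluded upstream).
#' @return Hours per patient-day.
#' @export
hppd <- function(staff_hours, patient_hours) {
  stopifnot(is.numeric(staff_hours), is.numeric(patient_hours))
  if (any(!is.finite(patient_hours)) || any(patient_hours <= 0)) {
    stop("`patient_hours` must be > 0: HPPD is undefined for an empty day",
         call. = FALSE)
  }
  staff_hours / (patient_hours / 24)
}

#' Daily staffing shortfall in HPPD
#'
#' Required minus deployed care hours, per patient-day.  Positive values
#' mean understaffing relative to the census-implied requirement;
#' negative values mean more staff were deployed than required.
#'
#' @param required_hours Required care hours (census-implied plus
#'   specialing).
#' @param deployed_hours Hours actually worked.
#' @inheritParams hppd
#' @return Signed shortfall in hours per patient-day.
#' @export
shortfall_hppd <- function(required_hours, deployed_hours, patient_hours) {
  hppd(required_hours - deployed_hours, patient_hours)
}

#' Patient turnover per staff hour
#'
#' Admissions plus discharges divided by the total care hours deployed
#' in the same 24-hour window.
#'
#' @param admissions,discharges Patient flow counts (>= 0).
#' @param total_staff_hours Total deployed care hours; must be > 0.
#' @return Patients moved per staff hour.
#' @export
turnover_per_staff_hour <- function(admissions, discharges, total_staff_hours) {
  stopifnot(is.numeric(admissions), is.numeric(discharges),
            all(admissions >= 0), all(discharges >= 0))
  if (any(!is.finite(total_staff_hours)) || any(total_staff_hours <= 0)) {
    stop("`total_staff_hours` must be > 0", call. = FALSE)
  }
  (admissions + discharges) / total_staff_hours
}

#' Day-level workload table from census and staffing records
#'
#' Joins one-row-per-unit-day census and staffing tables and derives the
#' full set of workload quantities: establishment (WTE), required hours
#' with and without specialing, the registered-nurse/assistant split by
#' the unit's skill-mix proxy, deployed and required HPPD, signed
#' shortfalls and turnover.  Days with zero patient-hours are dropped
#' with a warning (HPPD undefined).
#'
#' @param census Data frame with columns `unit_id`, `date`,
#'   `n_level*` count columns (one per level, in level order),
#'   `admin_count_0700`, `patient_hours`, `admissions`, `discharges`,
#'   `specialing_count`.
#' @param staffing Data frame with columns `unit_id`, `date`,
#'   `rn_hours`, `na_hours`.
#' @param ms An [multiplier_set()].
#' @param skill_mix Optional data frame `unit_id`, `skill_mix` giving
#'   the planned-skill-mix proxy per unit.  When `NULL`, the observed
#'   average mix `sum(rn) / sum(rn + na)` per unit is used, as a proxy
#'   for the planned mix.
#' @return A tibble with one row per linkable unit-day, carrying the
#'   input keys plus `establishment_wte`, `required_daily_hours`,
#'   `required_rn_hours`, `required_na_hours`, `deployed_hours`,
#'   `total_hppd`, `requirement_hppd` (including specialing, the basis
#'   of shortfalls), `establishment_hppd` (the establishment-implied
#'   requirement, excluding specialing), `rn_shortfall_hppd`,
#'   `na_shortfall_hppd`, `total_shortfall_hppd`, `turnover` and
#'   `skill_mix`.
#' @export
compute_workload <- function(census, staffing, ms = multiplier_set(),
                             skill_mix = NULL) {
  count_cols <- paste0("n_level", gsub("[^0-9a-z]", "", tolower(ms$levels)))
  needed <- c("unit_id", "date", count_cols, "admin_count_0700",
              "patient_hours", "admissions", "discharges", "specialing_count")
  missing_cols <- setdiff(needed, names(census))
  if (length(missing_cols) > 0) {
    stop("census is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(skill_mix)) {
    skill_mix <- unit_skill_mix(staffing)
  }
  stopifnot(all(c("unit_id", "skill_mix") %in% names(skill_mix)))

  dat <- dplyr::inner_join(census, staffing, by = c("unit_id", "date"))
  dat <- dplyr::left_join(dat, skill_mix, by = "unit_id")

  bad <- !is.finite(dat$patient_hours) | dat$patient_hours <= 0
  if (any(bad)) {
    warning(sum(bad), " unit-day(s) with zero patient-hours excluded ",
            "(HPPD undefined)", call. = FALSE)
    dat <- dat[!bad, , drop = FALSE]
  }

  cmat <- as.matrix(dat[count_cols])
  tot <- rowSums(cmat)
  empty <- tot <= 0
  if (any(empty & dat$admin_count_0700 > 0)) {
    stop("empty shift-leader census with nonzero administrative count on ",
         sum(empty & dat$admin_count_0700 > 0), " unit-day(s)", call. = FALSE)
  }
  wm <- rep(NA_real_, nrow(dat))
  wm[!empty] <- as.vector(cmat[!empty, , drop = FALSE] %*% ms$multipliers) /
    tot[!empty]

  est <- ifelse(dat$admin_count_0700 == 0, 0, wm * dat$admin_count_0700)
  req_base <- establishment_to_daily_hours(est, ms)
  req_total <- req_base +
    dat$specialing_count * ms$specialing_hours_per_patient_day
  split <- split_by_skill_mix(req_total, dat$skill_mix)
  deployed <- dat$rn_hours + dat$na_hours
  pd <- dat$patient_hours / 24

  tibble::tibble(
    unit_id = dat$unit_id,
    date = dat$date,
    skill_mix = dat$skill_mix,
    weighted_multiplier = wm,
    establishment_wte = est,
    required_daily_hours = req_total,
    required_rn_hours = split$rn,
    required_na_hours = split$na,
    deployed_hours = deployed,
    rn_hours = dat$rn_hours,
    na_hours = dat$na_hours,
    patient_hours = dat$patient_hours,
    total_hppd = deployed / pd,
    requirement_hppd = req_total / pd,
    establishment_hppd = req_base / pd,
    rn_shortfall_hppd = (split$rn - dat$rn_hours) / pd,
    na_shortfall_hppd = (split$na - dat$na_hours) / pd,
    total_shortfall_hppd = (req_total - deployed) / pd,
    turnover = (dat$admissions + dat$discharges) / pmax(deployed, 1e-9),
    admissions = dat$admissions,
    discharges = dat$discharges,
    specialing_count = dat$specialing_count,
    admin_count_0700 = dat$admin_count_0700
  )
}

#' Observed average skill mix per unit
#'
#' The proportion of deployed care hours worked by registered nurses,
#' aggregated over all days for each unit; used as the proxy for the
#' planned skill mix.
#'
#' @param staffing Data frame with `unit_id`, `rn_hours`, `na_hours`.
#' @return Tibble `unit_id`, `skill_mix`.
#' @export
unit_skill_mix <- function(staffing) {
  staffing |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      skill_mix = sum(.data$rn_hours) /
        pmax(sum(.data$rn_hours) + sum(.data$na_hours), 1e-9),
      .groups = "drop"
    )
}
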