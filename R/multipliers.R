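#' SNCT multiplier sets
#'
#' A multiplier set bundles the constants needed to turn a patient
#' acuity/dependency census into a staffing requirement: one whole-time
#' equivalent (WTE) weight per acuity level, the establishment "uplift"
#' covering annual leave, study time and sickness, the contracted weekly
#' hours of one WTE, and the care hours implied by one-to-one
#' ("specialing") supervision of a single patient for a day.
#'
#' The default values are the published multipliers for general adult
#' inpatient units with a 22% uplift and a 37.5-hour working week.  They
#' also ship as an editable YAML file in
#' `system.file("extdata", "multipliers.yaml", package = "wardstaff")`.
#'
#' @param levels Character vector of acuity level labels, lowest to
#'   highest dependency.
#' @param multipliers Numeric vector of WTE per patient, one per level,
#'   all strictly positive.
#' @param uplift_fraction Fraction added on top of the base establishment
#'   for leave/sickness cover (0.22 means +22%).
#' @param wte_weekly_hours Contracted hours per week for one WTE.
#' @param specialing_hours_per_patient_day Care hours required per
#'   one-to-one supervised patient per day.
#'
#' @return An object of class `snct_multipliers`.
#' @examples
#' ms <- multiplier_set()
#' ms$multipliers
#' @export
multiplier_set <- function(levels = c("0", "1a", "1b", "2", "3"),
                           multipliers = c(0.99, 1.39, 1.72, 1.97, 5.96),
                           uplift_fraction = 0.22,
                           wte_weekly_hours = 37.5,
                           specialing_hours_per_patient_day = 24) {
  levels <- as.character(levels)
  multipliers <- as.numeric(multipliers)
  if (length(levels) < 1L) {
    stop("at least one acuity level is required", call. = FALSE)
  }
  if (length(multipliers) != length(levels)) {
    stop("`multipliers` must have one entry per level", call. = FALSE)
  }
  if (anyDuplicated(levels)) {
    stop("level labels must be unique", call. = FALSE)
  }
  if (any(!is.finite(multipliers)) || any(multipliers <= 0)) {
    stop("all multipliers must be finite and > 0", call. = FALSE)
  }
  stopifnot(
    is.numeric(uplift_fraction), length(uplift_fraction) == 1L,
    is.finite(uplift_fraction), uplift_fraction >= 0,
    is.numeric(wte_weekly_hours), length(wte_weekly_hours) == 1L,
    is.finite(wte_weekly_hours), wte_weekly_hours > 0,
    is.numeric(specialing_hours_per_patient_day),
    specialing_hours_per_patient_day >= 0
  )
  structure(
    list(
      levels = levels,
      multipliers = stats::setNames(multipliers, levels),
      uplift_fraction = uplift_fraction,
      wte_weekly_hours = wte_weekly_hours,
      specialing_hours_per_patient_day = specialing_hours_per_patient_day
    ),
    class = "snct_multipliers"
  )
}

#' @export
print.snct_multipliers <- function(x, ...) {
  cat("SNCT multiplier set\n")
  cat("  levels:     ", paste(x$levels, collapse = ", "), "\n")
  cat("  multipliers:", paste(format(x$multipliers), collapse = ", "), "\n")
  cat(sprintf("  uplift: %.0f%%   WTE week: %g h   specialing: %g h/patient-day\n",
              100 * x$uplift_fraction, x$wte_weekly_hours,
              x$specialing_hours_per_patient_day))
  invisible(x)
}

#' Read or write a multiplier set as YAML
#'
#' The YAML layout has keys `levels`, `multipliers`, `uplift_fraction`,
#' `wte_weekly_hours` and `specialing_hours_per_patient_day`.
#'
#' @param path File path.  `read_multipliers()` defaults to the copy of
#'   the published general-ward multipliers installed with the package.
#' @return `read_multipliers()` returns an `snct_multipliers` object;
#'   `write_multipliers()` returns `path` invisibly.
#' @export
read_multipliers <- function(path = system.file("extdata", "multipliers.yaml",
                                                package = "wardstaff")) {
  cfg <- yaml::read_yaml(path)
  multiplier_set(
    levels = cfg$levels,
    multipliers = cfg$multipliers,
    uplift_fraction = cfg$uplift_fraction,
    wte_weekly_hours = cfg$wte_weekly_hours,
    specialing_hours_per_patient_day = cfg$specialing_hours_per_patient_day
  )
}

#' @param ms An `snct_multipliers` object.
#' @rdname read_multipliers
#' @export
write_multipliers <- function(ms, path) {
  stopifnot(inherits(ms, "snct_multipliers"))
  yaml::write_yaml(
    list(
      levels = ms$levels,
      multipliers = unname(ms$multipliers),
      uplift_fraction = ms$uplift_fraction,
      wte_weekly_hours = ms$wte_weekly_hours,
      specialing_hours_per_patient_day = ms$specialing_hours_per_patient_day
    ),
    path
  )
  invisible(path)
}
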