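#' Select the assessment to use for each unit-day
#'
#' Units record acuity censuses at least twice a day; the analysis uses
#' the first available rating each day (normally the morning one, with a
#' later assessment substituting when the morning rating is missing).
#'
#' @param assessments Data frame with `unit_id`, `date` and a
#'   zero-padded `"HH:MM"` `assessment_time` column, one row per
#'   recorded assessment.
#' @return One row per unit-day: the earliest assessment of the day.
#'   Days with no assessment at all simply have no row and are treated
#'   as missing downstream.
#' @export
select_daily_assessment <- function(assessments) {
  stopifnot(all(c("unit_id", "date", "assessment_time") %in%
                  names(assessments)))
  assessments |>
    dplyr::group_by(.data$unit_id, .data$date) |>
    dplyr::slice_min(.data$assessment_time, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Remove extreme staffing-shortfall days
#'
#' Drops unit-days whose shortfall lies outside mean +/- `k_sd` standard
#' deviations, computed within each unit (the rule targets atypical
#' periods for *that* ward, e.g. partial closures or gross recording
#' errors).  With a within-unit SD of zero (or fewer than two defined
#' days) nothing is removed for that unit.
#'
#' @param days Data frame of linked unit-days containing `unit_id` and
#'   the shortfall column.
#' @param col Name of the shortfall column
#'   (default `"total_shortfall_hppd"`).
#' @param k_sd Number of standard deviations (default 3).
#' @param by_unit Apply the rule within units (default) or pooled.
#' @return A list with the two disjoint partitions `kept` and `removed`
#'   (their union is the input) for audit.
#' @export
remove_shortfall_outliers <- function(days, col = "total_shortfall_hppd",
                                      k_sd = 3, by_unit = TRUE) {
  stopifnot(col %in% names(days), k_sd > 0)
  x <- days[[col]]
  grp <- if (by_unit) days$unit_id else rep("all", nrow(days))
  keep <- rep(TRUE, nrow(days))
  for (g in unique(grp)) {
    i <- which(grp == g & is.finite(x))
    if (length(i) < 2) next
    m <- mean(x[i])
    s <- stats::sd(x[i])
    if (!is.finite(s) || s == 0) next
    keep[i] <- abs(x[i] - m) <= k_sd * s
  }
  list(kept = days[keep, , drop = FALSE],
       removed = days[!keep, , drop = FALSE])
}

#' Split a unit's data at major reconfigurations
#'
#' When a unit moves, changes specialty or changes bed numbers partway
#' through the study, its data before and after the change are treated
#' as separate units.  Each segment receives a derived unit id
#' (`"<unit>/a"`, `"<unit>/b"`, ...); a unit with no change events keeps
#' its original id.  Segments shorter than `min_days` are dropped, since
#' they are too short to support even the minimum 20-day audit analyses.
#'
#' @param data Data frame with `unit_id` and `date` (plus anything
#'   else, carried through).
#' @param events Data frame with `unit_id` and `date`: the date each
#'   change takes effect (days on or after it belong to the next
#'   segment).  Events for unknown units are ignored.
#' @param min_days Minimum segment length to keep (default 28).
#' @return A list: `data` (with rewritten `unit_id`), and `segments`, a
#'   tibble describing every segment (`unit_id`, `derived_id`, `start`,
#'   `end`, `n_days`, `kept`).
#' @export
split_units_on_change <- function(data, events, min_days = 28) {
  stopifnot(all(c("unit_id", "date") %in% names(data)))
  if (is.null(events) || nrow(events) == 0) {
    seg <- data |>
      dplyr::group_by(.data$unit_id) |>
      dplyr::summarise(derived_id = .data$unit_id[1],
                       start = min(.data$date), end = max(.data$date),
                       n_days = dplyr::n(), kept = TRUE, .groups = "drop")
    return(list(data = data, segments = seg))
  }
  stopifnot(all(c("unit_id", "date") %in% names(events)))
  events <- events[events$unit_id %in% data$unit_id, , drop = FALSE]

  cuts <- split(events$date, events$unit_id)
  seg_of <- function(unit, date) {
    k <- cuts[[unit]]
    if (is.null(k)) return(1L)
    1L + findInterval(as.numeric(date), sort(as.numeric(k)))
  }
  seg_idx <- mapply(seg_of, data$unit_id, data$date)
  has_change <- data$unit_id %in% names(cuts)
  derived <- ifelse(has_change,
                    paste0(data$unit_id, "/", letters[seg_idx]),
                    data$unit_id)
  out <- data
  out$unit_id <- derived

  segments <- out |>
    dplyr::group_by(derived_id = .data$unit_id) |>
    dplyr::summarise(start = min(.data$date), end = max(.data$date),
                     n_days = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(unit_id = sub("/[a-z]+$", "", .data$derived_id),
                  kept = .data$n_days >= min_days) |>
    dplyr::select("unit_id", "derived_id", "start", "end", "n_days", "kept")
  dropped <- segments$derived_id[!segments$kept]
  if (length(dropped) > 0) {
    message("dropping ", length(dropped), " segment(s) shorter than ",
            min_days, " days: ", paste(dropped, collapse = ", "))
    out <- out[!out$unit_id %in% dropped, , drop = FALSE]
  }
  list(data = out, segments = segments)
}

#' Detect (and recode) units with reverse-coded adequacy responses
#'
#' Some units were found to have entered the three yes/no staffing
#' adequacy answers with the 0/1 coding inverted, due to erroneous
#' training.  Consistent inversion of all three answers leaves
#' between-answer correlations untouched, so detection rests on marginal
#' rates moving to the opposite side of 0.5 from the fleet: a unit is
#' flagged when at least two of the three reversal indicators hold:
#'
#' * its "enough staff" rate is below 0.5 while the fleet median rate is
#'   above 0.5;
#' * its "care left undone" rate is above 0.5 while the fleet median is
#'   below 0.5;
#' * its "breaks missed" rate is above 0.5 while the fleet median is
#'   below 0.5.
#'
#' Requiring two concordant reversals protects honestly low-adequacy
#' units (a ward that often lacks staff has a low "enough staff" rate
#' but does not report care left undone on most days).  The sign of the
#' within-unit association between "enough staff" and the day's staffing
#' shortfall (expected negative; positive after inversion) is recorded
#' per unit as a diagnostic.  Units with fewer than `min_days` responded
#' days are never flagged (a warning lists them).
#'
#' @param responses Data frame with `unit_id`, `date`, and 0/1 columns
#'   `enough_staff`, `care_left_undone`, `breaks_missed` (NA allowed).
#' @param shortfalls Optional data frame with `unit_id`, `date`,
#'   `total_shortfall_hppd`, used only for the association diagnostic.
#' @param min_days Minimum responded days to assess a unit (default 30).
#' @return `detect_reverse_coding()` returns a tibble per unit with the
#'   three rates, the reversal indicators, the shortfall association and
#'   `flagged`.  `recode_reverse_coding()` inverts all three answers for
#'   the given units.  `detect_and_recode_reverse_coding()` combines the
#'   two and returns `list(responses, flagged_units, details)`.
#' @export
detect_reverse_coding <- function(responses, shortfalls = NULL,
                                  min_days = 30) {
  outcome_cols <- c("enough_staff", "care_left_undone", "breaks_missed")
  stopifnot(all(c("unit_id", outcome_cols) %in% names(responses)))
  per_unit <- responses |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      n_responded = sum(stats::complete.cases(
        .data$enough_staff, .data$care_left_undone, .data$breaks_missed)),
      rate_enough = mean(.data$enough_staff, na.rm = TRUE),
      rate_undone = mean(.data$care_left_undone, na.rm = TRUE),
      rate_breaks = mean(.data$breaks_missed, na.rm = TRUE),
      .groups = "drop"
    )
  med <- list(enough = stats::median(per_unit$rate_enough, na.rm = TRUE),
              undone = stats::median(per_unit$rate_undone, na.rm = TRUE),
              breaks = stats::median(per_unit$rate_breaks, na.rm = TRUE))
  per_unit <- per_unit |>
    dplyr::mutate(
      rev_enough = .data$rate_enough < 0.5 & med$enough > 0.5,
      rev_undone = .data$rate_undone > 0.5 & med$undone < 0.5,
      rev_breaks = .data$rate_breaks > 0.5 & med$breaks < 0.5,
      assessable = .data$n_responded >= min_days,
      flagged = .data$assessable &
        (.data$rev_enough + .data$rev_undone + .data$rev_breaks) >= 2
    )
  if (any(!per_unit$assessable)) {
    warning(sum(!per_unit$assessable), " unit(s) with < ", min_days,
            " responded days left unassessed for reverse coding",
            call. = FALSE)
  }
  per_unit$shortfall_association <- NA_real_
  if (!is.null(shortfalls)) {
    joined <- dplyr::inner_join(
      responses, shortfalls[, c("unit_id", "date", "total_shortfall_hppd")],
      by = c("unit_id", "date")
    )
    assoc <- joined |>
      dplyr::group_by(.data$unit_id) |>
      dplyr::summarise(
        shortfall_association = tryCatch(
          suppressWarnings(stats::cor(.data$enough_staff,
                                      .data$total_shortfall_hppd,
                                      use = "complete.obs")),
          error = function(e) NA_real_),
        .groups = "drop"
      )
    per_unit$shortfall_association <- NULL
    per_unit <- dplyr::left_join(per_unit, assoc, by = "unit_id")
  }
  per_unit
}

#' @param units Character vector of unit ids to invert.
#' @rdname detect_reverse_coding
#' @export
recode_reverse_coding <- function(responses, units) {
  unknown <- setdiff(units, unique(responses$unit_id))
  if (length(unknown) > 0) {
    stop("unknown unit(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  i <- responses$unit_id %in% units
  for (col in c("enough_staff", "care_left_undone", "breaks_missed")) {
    responses[[col]][i] <- 1L - as_binary01(responses[[col]][i], col)
  }
  responses
}

#' @rdname detect_reverse_coding
#' @export
detect_and_recode_reverse_coding <- function(responses, shortfalls = NULL,
                                             min_days = 30) {
  details <- detect_reverse_coding(responses, shortfalls, min_days)
  flagged <- details$unit_id[details$flagged]
  if (length(flagged) > 0) {
    responses <- recode_reverse_coding(responses, flagged)
  }
  list(responses = responses, flagged_units = flagged, details = details)
}

#' Link censuses, staffing and next-morning adequacy responses
#'
#' Builds the day-level analysis table: the workload derived from the
#' census and roster for the 07:00-to-07:00 window starting on day *d*
#' is joined to the staffing-adequacy answers recorded the following
#' morning (day *d* + 1), which cover the preceding 24 hours.  Unit
#' covariates (hospital, specialty, single-room proportion) come from
#' the unit profile table, and day of week is derived from the staffing
#' date with Monday as the reference level.
#'
#' @inheritParams compute_workload
#' @param responses Adequacy responses (`unit_id`, `date`,
#'   `enough_staff`, `care_left_undone`, `breaks_missed`), dated the
#'   morning they were given.  `NULL` builds the covariate table with
#'   no outcome columns (used when outcomes are yet to be simulated).
#' @param profiles Unit profile table with `unit_id`, `hospital_id`,
#'   `specialty` (`"surgical"` vs `"medical"`/`"mixed"`) and
#'   `single_room_prop`.
#' @return A tibble of linked unit-days (workload columns plus
#'   `hospital_id`, `surgical`, `single_room_prop`, `day_of_week` and
#'   the three outcome columns, NA where no response was recorded).
#'   Attributes `n_unmatched_census`, `n_unmatched_staffing` and
#'   `n_orphan_responses` count records that could not be linked.
#' @export
link_days <- function(census, staffing, responses = NULL, profiles,
                      ms = multiplier_set(), skill_mix = NULL) {
  for (tab in list(census, staffing)) {
    dup <- duplicated(tab[c("unit_id", "date")])
    if (any(dup)) {
      keys <- unique(paste(tab$unit_id[dup], tab$date[dup]))
      stop("duplicate unit-day keys: ",
           paste(utils::head(keys, 5), collapse = "; "), call. = FALSE)
    }
  }
  wl <- compute_workload(census, staffing, ms, skill_mix)
  prof_cols <- c("unit_id", "hospital_id", "specialty", "single_room_prop")
  stopifnot(all(prof_cols %in% names(profiles)))
  linked <- dplyr::left_join(wl, profiles[prof_cols], by = "unit_id")
  linked$surgical <- as.integer(linked$specialty == "surgical")
  wd <- as.integer(format(as.Date(linked$date), "%u"))
  linked$day_of_week <- factor(
    c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[wd],
    levels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  )

  if (!is.null(responses)) {
    resp <- responses
    resp$date <- as.Date(resp$date) - 1L  # morning report covers previous day
    resp <- resp[, c("unit_id", "date", "enough_staff", "care_left_undone",
                     "breaks_missed")]
    linked <- dplyr::left_join(linked, resp, by = c("unit_id", "date"))
    attr(linked, "n_orphan_responses") <-
      nrow(resp) - nrow(dplyr::semi_join(resp, wl, by = c("unit_id", "date")))
  }

  attr(linked, "n_unmatched_census") <-
    nrow(census) - nrow(dplyr::semi_join(census, staffing,
                                         by = c("unit_id", "date")))
  attr(linked, "n_unmatched_staffing") <-
    nrow(staffing) - nrow(dplyr::semi_join(staffing, census,
                                           by = c("unit_id", "date")))
  linked
}
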