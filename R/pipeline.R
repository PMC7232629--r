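#' Configure a full pipeline run
#'
#' A run either reads the three day-level CSV tables plus a unit
#' profile table from `paths`, or generates them with the synthetic
#' study generator (`generator`).  Exactly one of the two must be
#' given.
#'
#' @param paths `NULL`, or a list with elements `census`, `staffing`,
#'   `responses`, `profiles` (CSV file paths) and optionally
#'   `multipliers` (YAML).
#' @param generator `NULL`, or a list with optional elements `config`
#'   ([fleet_config()]), `calibration` ([calibration_profile()]),
#'   `truth` ([adequacy_truth()]), `missingness`,
#'   `reverse_coded_units`, passed to [simulate_study()].
#' @param outcomes Adequacy outcomes to model.
#' @param univariable Also fit one-term models for the unadjusted
#'   odds-ratio column (slower).
#' @param sample_sizes Audit lengths for the precision sweep.
#' @param n_boot Bootstrap resamples per unit and audit length.
#' @param outlier_k_sd SD multiplier of the extreme-shortfall rule.
#' @param detect_reverse_coding Run reverse-coding detection/recoding.
#' @param exclude_hospital Optional hospital dropped from the model
#'   stage (sensitivity analysis).
#' @param seed Master seed; every stochastic stage derives its own
#'   seed from it (see [derive_seed()]).
#' @param outdir Output directory (created if needed), or `NULL` to
#'   skip writing files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(paths = NULL, generator = NULL,
                       outcomes = c("enough_staff", "care_left_undone",
                                    "breaks_missed"),
                       univariable = FALSE,
                       sample_sizes = seq(20, 180, by = 20),
                       n_boot = 1000, outlier_k_sd = 3,
                       detect_reverse_coding = TRUE,
                       exclude_hospital = NULL,
                       seed = 1, outdir = NULL) {
  if (is.null(paths) && is.null(generator)) {
    stop("run_config needs either `paths` to input tables or a ",
         "`generator` description", call. = FALSE)
  }
  structure(
    list(paths = paths, generator = generator, outcomes = outcomes,
         univariable = univariable, sample_sizes = sample_sizes,
         n_boot = n_boot, outlier_k_sd = outlier_k_sd,
         detect_reverse_coding = detect_reverse_coding,
         exclude_hospital = exclude_hospital, seed = seed,
         outdir = outdir),
    class = "run_config"
  )
}

#' Run the full staffing analysis pipeline
#'
#' Executes, in order: data acquisition (generate or read), selection
#' of the first daily assessment, linkage of census, roster and
#' next-morning responses, cleaning (extreme-shortfall days,
#' reverse-coding detection and recoding), the bootstrap precision
#' sweep, the adequacy models, and the summary table.  A manifest
#' records the seed and row counts at every stage; with a fixed seed
#' the deterministic outputs are bit-identical across reruns.
#'
#' @param config A [run_config()].
#' @return A list with `tables` (census, staffing, responses,
#'   profiles), `linked` (cleaned analysis table), `cleaning` (outlier
#'   partitions, reverse-coding details), `precision` (sweep summary),
#'   `fits` (per outcome), `table1` and `manifest`.  When
#'   `config$outdir` is set the standard CSV/JSON artefacts are also
#'   written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  manifest <- list(seed = seed)

  ms <- multiplier_set()
  if (!is.null(config$paths)) {
    p <- config$paths
    if (!is.null(p$multipliers)) ms <- read_multipliers(p$multipliers)
    tables <- list(
      assessments = read_census(p$census),
      staffing = read_staffing(p$staffing),
      responses = read_responses(p$responses),
      profiles = readr::read_csv(p$profiles, show_col_types = FALSE)
    )
  } else {
    g <- config$generator
    study <- simulate_study(
      config = g$config %||% fleet_config(),
      calibration = g$calibration %||% calibration_profile(),
      truth = g$truth %||% adequacy_truth(),
      ms = ms, seed = seed,
      missingness = if ("missingness" %in% names(g)) g$missingness else
        list(r_assessment = 0.04, r_response = 0.15),
      reverse_coded_units = g$reverse_coded_units
    )
    tables <- study[c("assessments", "staffing", "responses", "profiles")]
  }
  manifest$rows_assessments <- nrow(tables$assessments)
  manifest$rows_staffing <- nrow(tables$staffing)
  manifest$rows_responses <- nrow(tables$responses)
  manifest$n_units <- nrow(tables$profiles)

  census <- select_daily_assessment(tables$assessments)
  manifest$rows_census_days <- nrow(census)

  linked <- link_days(census, tables$staffing, tables$responses,
                      tables$profiles, ms = ms)
  manifest$rows_linked <- nrow(linked)

  outliers <- remove_shortfall_outliers(linked, k_sd = config$outlier_k_sd)
  linked <- outliers$kept
  manifest$rows_outliers_removed <- nrow(outliers$removed)
  manifest$rows_after_outliers <- nrow(linked)
  stopifnot(manifest$rows_after_outliers + manifest$rows_outliers_removed ==
              manifest$rows_linked)

  rc <- NULL
  if (isTRUE(config$detect_reverse_coding)) {
    rc <- detect_and_recode_reverse_coding(
      tables$responses,
      shortfalls = dplyr::mutate(
        linked[c("unit_id", "date", "total_shortfall_hppd")],
        date = as.Date(.data$date) + 1L  # response date for the same day
      )
    )
    tables$responses <- rc$responses
    manifest$reverse_coded_units <- rc$flagged_units
    # refresh the outcome columns with the recoded answers
    linked$enough_staff <- NULL
    linked$care_left_undone <- NULL
    linked$breaks_missed <- NULL
    resp <- dplyr::mutate(rc$responses, date = as.Date(.data$date) - 1L)
    linked <- dplyr::left_join(
      linked,
      resp[c("unit_id", "date", "enough_staff", "care_left_undone",
             "breaks_missed")],
      by = c("unit_id", "date")
    )
  }
  manifest$rows_with_outcome <- sum(!is.na(linked$enough_staff))

  precision <- precision_sweep(
    linked[c("unit_id", "establishment_wte")],
    sample_sizes = config$sample_sizes, n_boot = config$n_boot,
    seed = derive_seed(seed, 5L)
  )

  fits <- list()
  for (oc in config$outcomes) {
    spec <- adequacy_spec(outcome = oc,
                          exclude_hospital = config$exclude_hospital)
    fits[[oc]] <- list(adjusted = fit_adequacy(spec, linked))
    if (isTRUE(config$univariable)) {
      fits[[oc]]$univariable <- lapply(
        stats::setNames(spec$fixed, spec$fixed),
        function(tm) univariable_or(tm, linked, outcome = oc)
      )
    }
  }

  tab1 <- make_table1(linked)
  result <- list(tables = tables, linked = linked,
                 cleaning = list(outliers_removed = outliers$removed,
                                 reverse_coding = rc),
                 precision = precision, fits = fits, table1 = tab1,
                 manifest = manifest)
  if (!is.null(config$outdir)) {
    write_run_outputs(result, config$outdir)
  }
  invisible(result)
}

#' Per-hospital summary of staffing levels and requirements
#'
#' Mean, minimum and maximum over units of each unit's average total
#' hours per patient day, skill mix (% registered nurse) and estimated
#' requirement in HPPD, by hospital and overall.
#'
#' @param linked Linked unit-day table with workload columns and
#'   `hospital_id`.
#' @return A tibble with one row per hospital plus an `"All"` row.
#' @export
make_table1 <- function(linked) {
  stopifnot("hospital_id" %in% names(linked))
  per_unit <- linked |>
    dplyr::group_by(.data$hospital_id, .data$unit_id) |>
    dplyr::summarise(
      total_hppd = mean(.data$total_hppd),
      skill_mix_pct = 100 * mean(.data$rn_hours) /
        mean(.data$rn_hours + .data$na_hours),
      requirement_hppd = mean(.data$establishment_hppd),
      .groups = "drop"
    )
  summarise_units <- function(d, label) {
    tibble::tibble(
      hospital = label,
      n_units = nrow(d),
      total_hppd_mean = mean(d$total_hppd),
      total_hppd_min = min(d$total_hppd),
      total_hppd_max = max(d$total_hppd),
      skill_mix_mean = mean(d$skill_mix_pct),
      skill_mix_min = min(d$skill_mix_pct),
      skill_mix_max = max(d$skill_mix_pct),
      requirement_hppd_mean = mean(d$requirement_hppd),
      requirement_hppd_min = min(d$requirement_hppd),
      requirement_hppd_max = max(d$requirement_hppd)
    )
  }
  rows <- lapply(split(per_unit, per_unit$hospital_id),
                 function(d) summarise_units(d, d$hospital_id[1]))
  dplyr::bind_rows(c(rows, list(summarise_units(per_unit, "All"))))
}

write_run_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(outdir, ...)
  readr::write_csv(result$tables$staffing, out("staffing.csv"))
  readr::write_csv(result$tables$responses, out("responses.csv"))
  readr::write_csv(result$tables$profiles, out("unit_profiles.csv"))
  readr::write_csv(result$tables$assessments, out("census.csv"))
  readr::write_csv(result$linked, out("linked_days.csv"))
  readr::write_csv(result$precision, out("precision_sweep.csv"))
  readr::write_csv(result$table1, out("table1.csv"))
  for (oc in names(result$fits)) {
    fit <- result$fits[[oc]]$adjusted
    tab <- fit$coef
    uni <- result$fits[[oc]]$univariable
    if (!is.null(uni)) {
      uni_or <- unlist(lapply(uni, function(f) {
        stats::setNames(f$coef$or[-1], f$coef$term[-1])
      }))
      tab$or_univar <- uni_or[tab$term]
    }
    readr::write_csv(tab, out(paste0("fit_", oc, ".csv")))
    jsonlite::write_json(
      list(outcome = oc, var_unit = fit$var_unit, var_hosp = fit$var_hosp,
           vpc_unit = fit$vpc_unit, vpc_hosp = fit$vpc_hosp,
           aic = fit$aic, bic = fit$bic, n_obs = fit$n_obs,
           n_units = fit$n_units, n_hospitals = fit$n_hospitals,
           converged = fit$converged),
      out(paste0("fit_", oc, ".json")), auto_unbox = TRUE, digits = NA
    )
  }
  cleaning_report <- list(
    rows_linked = result$manifest$rows_linked,
    outlier_days_removed = result$manifest$rows_outliers_removed,
    outlier_pct = 100 * result$manifest$rows_outliers_removed /
      max(result$manifest$rows_linked, 1),
    reverse_coded_units = result$manifest$reverse_coded_units %||%
      character()
  )
  jsonlite::write_json(cleaning_report, out("cleaning_report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Assemble a markdown report from a run directory
#'
#' Collects the CSV artefacts written by [run_pipeline()] into a
#' single human-readable markdown report (summary table, precision
#' sweep, model odds ratios).  Sections whose artefact is missing are
#' marked absent rather than failing the report.
#'
#' @param outdir Run directory.
#' @param file Report path (default `report.md` inside `outdir`).
#' @return The report path, invisibly.
#' @export
make_report <- function(outdir, file = file.path(outdir, "report.md")) {
  if (!dir.exists(outdir) || length(list.files(outdir)) == 0) {
    stop("run directory is empty: ", outdir, call. = FALSE)
  }
  lines <- c("# Ward staffing analysis report", "")
  add_csv <- function(lines, path, title, digits = 2) {
    lines <- c(lines, paste("##", title), "")
    if (!file.exists(path)) {
      return(c(lines, "_Not produced in this run._", ""))
    }
    d <- readr::read_csv(path, show_col_types = FALSE)
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], round, digits)
    header <- paste("|", paste(names(d), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(d)), collapse = " | "), "|")
    body <- apply(d, 1, function(r) paste("|", paste(r, collapse = " | "),
                                          "|"))
    c(lines, header, sep, body, "")
  }
  manifest_path <- file.path(outdir, "manifest.json")
  if (file.exists(manifest_path)) {
    m <- jsonlite::read_json(manifest_path)
    lines <- c(lines, sprintf("Seed %s; %s linked unit-days (%s with an outcome).",
                              m$seed, m$rows_after_outliers,
                              m$rows_with_outcome), "")
  }
  lines <- add_csv(lines, file.path(outdir, "table1.csv"),
                   "Unit staffing levels and estimated requirements", 1)
  lines <- add_csv(lines, file.path(outdir, "precision_sweep.csv"),
                   "Precision of establishment estimates by audit length", 1)
  for (oc in c("enough_staff", "care_left_undone", "breaks_missed")) {
    lines <- add_csv(lines, file.path(outdir, paste0("fit_", oc, ".csv")),
                     paste("Adequacy model:", gsub("_", " ", oc)), 2)
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read the standard day-level CSV tables
#'
#' Readers for the three day-level interchange tables.  Dates are
#' ISO-8601; the observation window is 07:00 to 07:00 by convention;
#' responses use 1 = yes, 0 = no.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_census <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(unit_id = "c", date = "D",
                                          assessment_time = "c",
                                          .default = "d"))
}

#' @rdname read_census
#' @export
read_staffing <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(unit_id = "c", date = "D",
                                          .default = "d"))
}

#' @rdname read_census
#' @export
read_responses <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(unit_id = "c", date = "D",
                                          response_time = "c",
                                          .default = "i"))
}
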