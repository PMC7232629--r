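#' Bootstrap precision of an establishment estimate
#'
#' Emulates a staffing audit of `n_days` days drawn from a unit's daily
#' establishment series: `n_boot` resamples of size `n_days` are drawn
#' with replacement (ignoring time order), the mean establishment is
#' computed for each, and a confidence interval for the mean is formed.
#' Precision is half the CI width expressed as a percentage of the
#' bootstrap mean, so a precision of 4% means the establishment is
#' estimated to within roughly +/-4%.
#'
#' @param values Numeric vector of daily establishment estimates (WTE)
#'   for one unit.
#' @param n_days Audit length (days per resample).
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param ci_level Confidence level, strictly between 0 and 1.
#' @param seed Optional integer seed; with a seed the result is
#'   bit-reproducible and the caller's RNG state is untouched.
#' @param method `"percentile"` (default) takes the 2.5/97.5 quantiles
#'   of the resample means with linear interpolation between order
#'   statistics; `"normal"` uses mean +/- z * sd of the resample means.
#' @return A one-row tibble: `n_series`, `n_days`, `n_boot`, `eligible`,
#'   `boot_mean`, `ci_low`, `ci_high`, `ci_width`, `precision_pct`.
#'   Units whose series is shorter than `n_days` are ineligible: the row
#'   is returned with `eligible = FALSE` and missing estimates rather
#'   than an error, so sweeps can record them.  `precision_pct` is
#'   missing when the bootstrap mean is zero.
#' @examples
#' bootstrap_establishment(rnorm(365, 35, 3.3), n_days = 20, seed = 1)
#' @export
bootstrap_establishment <- function(values, n_days = 20, n_boot = 1000,
                                    ci_level = 0.95, seed = NULL,
                                    method = c("percentile", "normal")) {
  method <- match.arg(method)
  stopifnot(is.numeric(values), n_boot >= 2,
            ci_level > 0, ci_level < 1, n_days >= 1)
  values <- values[is.finite(values)]
  out <- tibble::tibble(
    n_series = length(values), n_days = as.integer(n_days),
    n_boot = as.integer(n_boot), eligible = length(values) >= n_days,
    boot_mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    ci_width = NA_real_, precision_pct = NA_real_
  )
  if (!out$eligible) {
    return(out)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  idx <- sample.int(length(values), n_days * n_boot, replace = TRUE)
  means <- colMeans(matrix(values[idx], nrow = n_days))
  bm <- mean(means)
  if (method == "percentile") {
    alpha <- (1 - ci_level) / 2
    ci <- unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
  } else {
    z <- stats::qnorm(1 - (1 - ci_level) / 2)
    ci <- bm + c(-1, 1) * z * stats::sd(means)
  }
  out$boot_mean <- bm
  out$ci_low <- ci[1]
  out$ci_high <- ci[2]
  out$ci_width <- ci[2] - ci[1]
  out$precision_pct <- if (bm == 0) NA_real_ else 100 * (out$ci_width / 2) / bm
  out
}

#' Precision of establishment estimates across audit lengths
#'
#' Runs [bootstrap_establishment()] for every unit at each audit length
#' and summarises, per length: the average CI width (WTE), the average
#' precision (%), and the number of units whose CI width is at most 1
#' and at most 2 WTE (i.e. within +/-0.5 and +/-1 WTE of the mean).
#' Units with fewer recorded days than the audit length are excluded
#' from that row's averages and counts, so the number of eligible units
#' is non-increasing in the sample size.
#'
#' @param series Either a named list of numeric establishment series, or
#'   a data frame with columns `unit_id` and `establishment_wte` (e.g.
#'   the output of [compute_workload()]), split by unit internally.
#' @param sample_sizes Ascending audit lengths (days).
#' @param seed Optional master seed; per-unit, per-size seeds are
#'   derived from it so any cell can be reproduced in isolation.
#' @inheritParams bootstrap_establishment
#' @return A tibble with columns `n_days`, `avg_ci_width_wte`,
#'   `avg_precision_pct`, `n_units_width_le_1`, `n_units_width_le_2`
#'   and `n_units`, one row per audit length, with the per-unit results
#'   attached as attribute `"by_unit"`.
#' @export
precision_sweep <- function(series, sample_sizes = seq(20, 180, by = 20),
                            n_boot = 1000, ci_level = 0.95, seed = NULL,
                            method = c("percentile", "normal")) {
  method <- match.arg(method)
  stopifnot(length(sample_sizes) > 0, !is.unsorted(sample_sizes))
  if (is.data.frame(series)) {
    stopifnot(all(c("unit_id", "establishment_wte") %in% names(series)))
    series <- split(series$establishment_wte, series$unit_id)
  }
  stopifnot(is.list(series), length(series) > 0, !is.null(names(series)))

  grid <- expand.grid(unit = names(series), n_days = sample_sizes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    u <- grid$unit[i]
    n <- grid$n_days[i]
    cell_seed <- if (is.null(seed)) NULL else {
      derive_seed(seed, match(u, names(series)) * 1000L + match(n, sample_sizes))
    }
    res <- bootstrap_establishment(series[[u]], n_days = n, n_boot = n_boot,
                                   ci_level = ci_level, seed = cell_seed,
                                   method = method)
    dplyr::mutate(res, unit_id = u, .before = 1)
  })
  by_unit <- dplyr::bind_rows(rows)

  summary <- by_unit |>
    dplyr::filter(.data$eligible) |>
    dplyr::group_by(n_days = .data$n_days) |>
    dplyr::summarise(
      avg_ci_width_wte = mean(.data$ci_width),
      avg_precision_pct = mean(.data$precision_pct),
      n_units_width_le_1 = sum(.data$ci_width <= 1),
      n_units_width_le_2 = sum(.data$ci_width <= 2),
      n_units = dplyr::n(),
      .groups = "drop"
    )
  # rows where no unit was eligible still appear, with null averages
  empty <- setdiff(sample_sizes, summary$n_days)
  if (length(empty) > 0) {
    summary <- dplyr::bind_rows(
      summary,
      tibble::tibble(n_days = as.integer(empty), avg_ci_width_wte = NA_real_,
                     avg_precision_pct = NA_real_, n_units_width_le_1 = 0L,
                     n_units_width_le_2 = 0L, n_units = 0L)
    )
  }
  summary <- dplyr::arrange(summary, .data$n_days)
  attr(summary, "by_unit") <- by_unit
  summary
}

#' Plot precision and CI width against audit length
#'
#' Line plot of mean precision (%) and mean CI width (WTE) from a
#' [precision_sweep()] summary, one panel per measure.
#'
#' @param sweep Output of [precision_sweep()].
#' @return A ggplot object.
#' @export
plot_precision_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(
    dplyr::select(sweep, "n_days", "avg_ci_width_wte", "avg_precision_pct"),
    -"n_days", names_to = "measure", values_to = "value"
  )
  long$measure <- factor(
    long$measure, c("avg_precision_pct", "avg_ci_width_wte"),
    labels = c("Mean precision (%)", "Mean 95% CI width (WTE)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_days, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Days sampled for the estimate", y = NULL) +
    ggplot2::theme_minimal()
}
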