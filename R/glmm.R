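#' Specify a staffing-adequacy model
#'
#' Describes one three-level logistic regression of a daily yes/no
#' adequacy outcome on staffing shortfalls and unit covariates, with
#' random intercepts for unit nested in hospital.  The default fixed
#' terms are the full adjustment set: registered-nurse and
#' nursing-assistant shortfalls (HPPD), patient turnover per staff
#' hour, surgical specialty (vs medical or mixed), proportion of single
#' rooms and day of week (Monday reference).  An alternative
#' parameterisation replaces the two shortfalls with the total-hours
#' shortfall plus skill mix.
#'
#' @param outcome One of `"enough_staff"`, `"care_left_undone"`,
#'   `"breaks_missed"`.
#' @param fixed Character vector of fixed-effect terms (columns of the
#'   linked-day table).  `total_shortfall_hppd` must not be combined
#'   with the registered-nurse/assistant pair it is the sum of.
#' @param quadratic Subset of staffing terms entered also as squares.
#' @param interactions List of length-2 character vectors: pairs of
#'   fixed terms whose interaction is added.
#' @param exclude_hospital Optional hospital id to drop before fitting
#'   (sensitivity analysis).
#' @return An object of class `adequacy_spec`.
#' @export
adequacy_spec <- function(outcome = c("enough_staff", "care_left_undone",
                                      "breaks_missed"),
                          fixed = c("rn_shortfall_hppd", "na_shortfall_hppd",
                                    "turnover", "surgical",
                                    "single_room_prop", "day_of_week"),
                          quadratic = character(),
                          interactions = list(),
                          exclude_hospital = NULL) {
  outcome <- match.arg(outcome)
  if ("total_shortfall_hppd" %in% fixed &&
      any(c("rn_shortfall_hppd", "na_shortfall_hppd") %in% fixed)) {
    stop("`total_shortfall_hppd` and the RN/NA shortfall pair are mutually ",
         "exclusive (the total is their sum)", call. = FALSE)
  }
  stopifnot(all(quadratic %in% fixed))
  structure(
    list(outcome = outcome, fixed = fixed, quadratic = quadratic,
         interactions = interactions, exclude_hospital = exclude_hospital),
    class = "adequacy_spec"
  )
}

spec_formula <- function(spec, with_hospital = TRUE) {
  rhs <- spec$fixed
  if (length(spec$quadratic) > 0) {
    rhs <- c(rhs, paste0("I(", spec$quadratic, "^2)"))
  }
  for (pair in spec$interactions) {
    rhs <- c(rhs, paste(pair, collapse = ":"))
  }
  re <- if (with_hospital) {
    "(1 | hospital_id) + (1 | unit_id)"
  } else {
    "(1 | unit_id)"
  }
  stats::as.formula(
    paste(spec$outcome, "~", paste(c(rhs, re), collapse = " + "))
  )
}

#' Fit a three-level staffing-adequacy model
#'
#' Fits the logistic mixed model described by an [adequacy_spec()] by
#' maximum likelihood with the Laplace approximation
#' ([lme4::glmer()]), with random intercepts for unit and hospital
#' (days nested in units nested in hospitals).  Standard errors and
#' p-values are Wald z-tests; odds ratios are per natural unit of each
#' covariate (per HPPD of shortfall, per unit proportion), matching how
#' the coefficients are reported.  Days with a missing outcome or
#' missing covariates are deleted listwise and counted.
#'
#' With a single hospital (e.g. after exclusion) the hospital level is
#' dropped with a warning.  A degenerate outcome (only one class
#' present) or complete separation on a categorical covariate is an
#' error; non-convergence is *not* an error but is flagged on the
#' result together with the optimizer messages.
#'
#' @param spec An [adequacy_spec()].
#' @param data Linked unit-day table (see [link_days()]).
#' @param nAGQ Integer passed to [lme4::glmer()] when only one random
#'   effect remains; ignored (Laplace, `nAGQ = 1`) for the nested pair,
#'   which lme4 only supports under the Laplace approximation.
#' @return An `adequacy_fit`: list with `coef` (tibble of term,
#'   estimate, se, z, p, or, ci_low, ci_high), `var_unit`, `var_hosp`,
#'   `vpc_unit`, `vpc_hosp`, `aic`, `bic`, `loglik`, `n_obs`,
#'   `n_units`, `n_hospitals`, `n_dropped`, `converged`, `messages`,
#'   `spec`, and the underlying `model`.
#' @export
fit_adequacy <- function(spec, data, nAGQ = 1) {
  stopifnot(inherits(spec, "adequacy_spec"))
  if (!is.null(spec$exclude_hospital)) {
    data <- data[!data$hospital_id %in% spec$exclude_hospital, , drop = FALSE]
  }
  used_cols <- c(spec$outcome, spec$fixed, "unit_id", "hospital_id")
  missing_cols <- setdiff(used_cols, names(data))
  if (length(missing_cols) > 0) {
    stop("data lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(data[used_cols])
  n_dropped <- sum(!keep)
  dat <- data[keep, used_cols, drop = FALSE]
  dat$unit_id <- factor(dat$unit_id)
  dat$hospital_id <- factor(dat$hospital_id)

  y <- as_binary01(dat[[spec$outcome]], spec$outcome)
  if (length(unique(y)) < 2) {
    stop("degenerate outcome: `", spec$outcome,
         "` takes a single value in the analysis data", call. = FALSE)
  }
  dat[[spec$outcome]] <- y
  check_separation(dat, spec$outcome, spec$fixed)

  with_hosp <- nlevels(dat$hospital_id) > 1
  if (!with_hosp) {
    warning("single hospital in data: hospital-level intercept dropped",
            call. = FALSE)
  }
  form <- spec_formula(spec, with_hospital = with_hosp)
  fit <- lme4::glmer(
    form, data = dat, family = stats::binomial(),
    control = lme4::glmerControl(optimizer = "bobyqa",
                                 calc.derivs = FALSE),
    nAGQ = if (with_hosp) 1 else nAGQ
  )

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  zc <- stats::qnorm(0.975)
  coef_tab <- tibble::tibble(
    term = names(beta), estimate = unname(beta), se = unname(se),
    z = unname(z), p = unname(p), or = exp(unname(beta)),
    ci_low = exp(unname(beta - zc * se)),
    ci_high = exp(unname(beta + zc * se))
  )

  vc <- lme4::VarCorr(fit)
  var_unit <- if ("unit_id" %in% names(vc)) as.numeric(vc$unit_id) else 0
  var_hosp <- if ("hospital_id" %in% names(vc)) {
    as.numeric(vc$hospital_id)
  } else {
    0
  }
  v <- vpc(var_unit, var_hosp)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)

  structure(
    list(
      coef = coef_tab,
      var_unit = var_unit, var_hosp = var_hosp,
      vpc_unit = unname(v["vpc_unit"]), vpc_hosp = unname(v["vpc_hosp"]),
      aic = stats::AIC(fit), bic = stats::BIC(fit),
      loglik = as.numeric(stats::logLik(fit)),
      n_obs = nrow(dat), n_units = nlevels(dat$unit_id),
      n_hospitals = nlevels(dat$hospital_id), n_dropped = n_dropped,
      converged = fit@optinfo$conv$opt == 0 && length(msgs) == 0,
      messages = msgs %||% character(),
      spec = spec, model = fit
    ),
    class = "adequacy_fit"
  )
}

check_separation <- function(dat, outcome, fixed) {
  for (term in fixed) {
    x <- dat[[term]]
    is_cat <- is.factor(x) || is.character(x) ||
      (is.numeric(x) && length(unique(x)) <= 2)
    if (!is_cat) next
    tab <- table(x, dat[[outcome]])
    if (nrow(tab) > 1 && any(tab == 0)) {
      stop("complete separation on `", term,
           "`: some level has a constant outcome", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.adequacy_fit <- function(x, ...) {
  cat("Three-level staffing-adequacy model: outcome", x$spec$outcome, "\n")
  cat(sprintf("  %d days in %d units in %d hospital(s); %d dropped\n",
              x$n_obs, x$n_units, x$n_hospitals, x$n_dropped))
  print(as.data.frame(x$coef), digits = 3)
  cat(sprintf("  var(unit) = %.3f  var(hospital) = %.3f  VPC %.3f / %.3f\n",
              x$var_unit, x$var_hosp, x$vpc_unit, x$vpc_hosp))
  cat(sprintf("  AIC %.1f  BIC %.1f  converged: %s\n",
              x$aic, x$bic, x$converged))
  invisible(x)
}

#' Univariable odds ratio from the multilevel model
#'
#' Enters a single covariate into the random-intercept model (unit in
#' hospital) with no other adjustment, as used for the unadjusted
#' column of the results table.
#'
#' @param term A single fixed-term name.
#' @inheritParams fit_adequacy
#' @param outcome Outcome column name.
#' @return An `adequacy_fit` with one fixed term.
#' @export
univariable_or <- function(term, data, outcome = "enough_staff") {
  fit_adequacy(adequacy_spec(outcome = outcome, fixed = term), data)
}

#' Variance partition coefficients for a two-level-plus-days logistic
#' model
#'
#' Under the latent-variable formulation the day-level residual of a
#' logistic model has variance \eqn{\pi^2/3}; each clustering level's
#' VPC is its variance over the common total
#' \eqn{\sigma^2_{unit} + \sigma^2_{hospital} + \pi^2/3}.
#' `vpc_to_variances()` inverts the pair of equations, recovering the
#' variances that yield given VPCs.
#'
#' @param var_unit,var_hosp Random-intercept variances (>= 0).
#' @return Named vector `c(vpc_unit, vpc_hosp)`, each in `[0, 1)`.
#' @examples
#' vpc(1.097, 0.598)  # ~ (0.220, 0.120)
#' @export
vpc <- function(var_unit, var_hosp) {
  stopifnot(var_unit >= 0, var_hosp >= 0)
  total <- var_unit + var_hosp + pi^2 / 3
  c(vpc_unit = var_unit / total, vpc_hosp = var_hosp / total)
}

#' @param vpc_unit,vpc_hosp Target variance partition coefficients,
#'   non-negative with sum < 1.
#' @rdname vpc
#' @export
vpc_to_variances <- function(vpc_unit, vpc_hosp) {
  stopifnot(vpc_unit >= 0, vpc_hosp >= 0, vpc_unit + vpc_hosp < 1)
  total <- (pi^2 / 3) / (1 - vpc_unit - vpc_hosp)
  c(var_unit = vpc_unit * total, var_hosp = vpc_hosp * total)
}

#' Express an odds ratio as a signed percent change in odds
#'
#' @param or_value Odds ratio(s), > 0.
#' @return `100 * (or_value - 1)`: -11 for OR 0.89, +14 for OR 1.14.
#' @export
or_to_percent_change <- function(or_value) {
  stopifnot(is.numeric(or_value), all(or_value > 0))
  100 * (or_value - 1)
}

#' Compare a linear shortfall model with its quadratic extension
#'
#' Refits the model with `term` also entered as a square, and compares
#' by AIC and BIC.  The two criteria can disagree (the quadratic term
#' may lower AIC while BIC's heavier penalty raises it); the comparison
#' is then reported as `"ambiguous"` rather than forced.
#'
#' @inheritParams fit_adequacy
#' @param term Staffing term to square (must be in `spec$fixed`).
#' @return List with `fit_linear`, `fit_quadratic`, `delta_aic`,
#'   `delta_bic` (quadratic minus linear), the Wald p-value of the
#'   squared term, and `preferred` (`"linear"`, `"quadratic"` or
#'   `"ambiguous"`).
#' @export
add_quadratic_and_compare <- function(spec, data,
                                      term = "rn_shortfall_hppd") {
  stopifnot(term %in% spec$fixed)
  fit_lin <- fit_adequacy(spec, data)
  spec_quad <- spec
  spec_quad$quadratic <- union(spec$quadratic, term)
  fit_quad <- fit_adequacy(spec_quad, data)
  d_aic <- fit_quad$aic - fit_lin$aic
  d_bic <- fit_quad$bic - fit_lin$bic
  quad_term <- paste0("I(", term, "^2)")
  p_quad <- fit_quad$coef$p[fit_quad$coef$term == quad_term]
  preferred <- if (d_aic < 0 && d_bic < 0) {
    "quadratic"
  } else if (d_aic > 0 && d_bic > 0) {
    "linear"
  } else {
    "ambiguous"
  }
  list(fit_linear = fit_lin, fit_quadratic = fit_quad,
       delta_aic = d_aic, delta_bic = d_bic, p_quadratic = p_quad,
       preferred = preferred)
}

#' Scan candidate interactions with staffing shortfalls
#'
#' Fits the base model plus each candidate interaction pair in turn and
#' reports the interaction's Wald p-value and the change in AIC/BIC
#' relative to the base model.
#'
#' @inheritParams fit_adequacy
#' @param candidate_pairs List of length-2 character vectors of fixed
#'   terms already in `spec$fixed`.
#' @return Tibble with one row per pair: `pair`, `estimate`, `p`,
#'   `delta_aic`, `delta_bic`, `significant` (p < 0.05).  Empty input
#'   gives an empty table.
#' @export
interaction_scan <- function(spec, data, candidate_pairs) {
  empty <- tibble::tibble(pair = character(), estimate = numeric(),
                          p = numeric(), delta_aic = numeric(),
                          delta_bic = numeric(), significant = logical())
  if (length(candidate_pairs) == 0) return(empty)
  base <- fit_adequacy(spec, data)
  rows <- lapply(candidate_pairs, function(pair) {
    stopifnot(length(pair) == 2, all(pair %in% spec$fixed))
    spec_i <- spec
    spec_i$interactions <- c(spec$interactions, list(pair))
    fit_i <- fit_adequacy(spec_i, data)
    lab <- paste(pair, collapse = ":")
    row <- fit_i$coef[grepl(":", fit_i$coef$term), ]
    row <- row[nrow(row), ]  # the added interaction is the last one
    tibble::tibble(pair = lab, estimate = row$estimate, p = row$p,
                   delta_aic = fit_i$aic - base$aic,
                   delta_bic = fit_i$bic - base$bic,
                   significant = row$p < 0.05)
  })
  dplyr::bind_rows(rows)
}

#' Predicted change in odds across a shortfall grid
#'
#' For a fitted model with a linear (and optionally quadratic) effect
#' of a staffing shortfall, computes the odds ratio relative to zero
#' shortfall over a grid, with a delta-method 95% band:
#' \eqn{\log OR(x) = \beta_1 x + \beta_2 x^2}.
#'
#' @param fit An `adequacy_fit` containing `term` (and possibly its
#'   square).
#' @param term Shortfall term name.
#' @param grid Numeric grid of shortfall values (HPPD).
#' @return Tibble `shortfall`, `odds_ratio`, `ci_low`, `ci_high`.
#' @export
shortfall_effect_curve <- function(fit, term = "rn_shortfall_hppd",
                                   grid = seq(-3, 3, by = 0.1)) {
  stopifnot(inherits(fit, "adequacy_fit"))
  quad_term <- paste0("I(", term, "^2)")
  terms_in <- intersect(c(term, quad_term), fit$coef$term)
  if (!term %in% terms_in) {
    stop("`", term, "` is not a fixed term of this fit", call. = FALSE)
  }
  V <- as.matrix(stats::vcov(fit$model))[terms_in, terms_in, drop = FALSE]
  b <- stats::setNames(fit$coef$estimate, fit$coef$term)[terms_in]
  X <- cbind(grid, if (quad_term %in% terms_in) grid^2)
  eta <- as.vector(X %*% b)
  se <- sqrt(rowSums((X %*% V) * X))
  zc <- stats::qnorm(0.975)
  tibble::tibble(
    shortfall = grid,
    odds_ratio = exp(eta),
    ci_low = exp(eta - zc * se),
    ci_high = exp(eta + zc * se)
  )
}

#' Plot the shortfall effect curve
#'
#' @param curve Output of [shortfall_effect_curve()].
#' @return A ggplot object: odds of the outcome relative to zero
#'   shortfall, with the delta-method band.
#' @export
plot_effect_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$shortfall,
                                      y = .data$odds_ratio)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Staffing shortfall (hours per patient day)",
                  y = "Odds ratio vs no shortfall") +
    ggplot2::theme_minimal()
}
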