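test_that("VPC arithmetic follows the latent-variable formulation", {
  v <- vpc(1.097, 0.598)
  expect_equal(unname(round(v, 3)), c(0.220, 0.120))
  expect_equal(unname(vpc(0, 0)), c(0, 0))
  expect_equal(unname(vpc(pi^2 / 3, 0)), c(0.5, 0))
  # inversion recovers the variances
  vv <- vpc_to_variances(0.22, 0.12)
  expect_equal(unname(round(vv, 3)), c(1.097, 0.598))
  expect_equal(unname(vpc(vv["var_unit"], vv["var_hosp"])), c(0.22, 0.12))
  # the two VPCs always sum below one
  withr::with_seed(51, {
    for (i in 1:20) {
      v2 <- vpc(runif(1, 0, 5), runif(1, 0, 5))
      expect_lt(sum(v2), 1)
    }
  })
})

test_that("odds-ratio percent-change transform and its reciprocal identity", {
  expect_equal(or_to_percent_change(0.89), -11)
  expect_equal(or_to_percent_change(1.14), 14)
  expect_equal(or_to_percent_change(1), 0)
  # 1/OR flips understaffing to overstaffing: -pc(x)/x, i.e. +12.36% at 0.89
  x <- 0.89
  expect_equal(or_to_percent_change(1 / x), -or_to_percent_change(x) / x)
  expect_equal(or_to_percent_change(1 / x), 12.36, tolerance = 1e-3)
  expect_error(or_to_percent_change(-1), "> 0")
})

# Shared small complete-data study for several model tests
glmm_fixture <- small_linked_study(seed = 201, days = 120)

test_that("degenerate outcomes and separation are refused with clear errors", {
  linked <- glmm_fixture$linked
  allyes <- dplyr::mutate(linked, enough_staff = 1L)
  expect_error(fit_adequacy(adequacy_spec("enough_staff"), allyes),
               "degenerate outcome")
  sep <- dplyr::mutate(linked,
                       enough_staff = ifelse(.data$surgical == 1, 1L,
                                             .data$enough_staff))
  expect_error(fit_adequacy(adequacy_spec("enough_staff"), sep),
               "separation on `surgical`")
  expect_error(
    adequacy_spec("enough_staff",
                  fixed = c("total_shortfall_hppd", "rn_shortfall_hppd")),
    "mutually exclusive"
  )
})

test_that("with zero planted variances the fit collapses to plain logistic", {
  zero_truth <- adequacy_truth()
  for (oc in names(zero_truth)) {
    zero_truth[[oc]]$var_unit <- 0
    zero_truth[[oc]]$var_hosp <- 0
    zero_truth[[oc]]$target_rate <- 0.6
  }
  fx <- small_linked_study(seed = 5, n_hospitals = 2, units_per_hospital = 10,
                           days = 150, truth = zero_truth)
  fit <- fit_adequacy(adequacy_spec("enough_staff"), fx$linked)
  g <- stats::glm(
    enough_staff ~ rn_shortfall_hppd + na_shortfall_hppd + turnover +
      surgical + single_room_prop + day_of_week,
    family = stats::binomial(), data = fx$linked
  )
  expect_lt(max(abs(fit$coef$estimate - stats::coef(g))), 1e-3)
  expect_lt(fit$var_unit, 1e-4)
  expect_lt(fit$var_hosp, 1e-4)
})

test_that("planted effects are recovered on average with honest CI coverage", {
  truth <- adequacy_truth()$enough_staff
  errs <- list()
  covered <- 0
  total <- 0
  for (s in 1:20) {
    fx <- small_linked_study(seed = 100 + s, days = 90)
    fit <- fit_adequacy(adequacy_spec("enough_staff"), fx$linked)
    tab <- fit$coef[fit$coef$term != "(Intercept)", ]
    tr <- truth$beta
    names(tr) <- sub("^dow", "day_of_week", names(tr))
    tr <- tr[match(tab$term, names(tr))]
    errs[[s]] <- tab$estimate - tr
    lo <- tab$estimate - 1.96 * tab$se
    hi <- tab$estimate + 1.96 * tab$se
    covered <- covered + sum(tr >= lo & tr <= hi)
    total <- total + length(tr)
  }
  err <- do.call(rbind, errs)
  mean_err <- colMeans(err)
  two_se <- 2 * apply(err, 2, stats::sd) / sqrt(nrow(err))
  # every fixed term: mean recovered coefficient within 2 empirical SEs
  expect_true(all(abs(mean_err) <= two_se),
              info = paste(names(mean_err)[abs(mean_err) > two_se],
                           collapse = ", "))
  cov_rate <- covered / total
  expect_gte(cov_rate, 0.90)
  expect_lte(cov_rate, 0.99)
})

test_that("AIC and BIC follow their definitions with k = fixed terms + 2", {
  fit <- fit_adequacy(adequacy_spec("enough_staff"), glmm_fixture$linked)
  k <- nrow(fit$coef) + 2  # fixed effects (incl. intercept) + two variances
  expect_equal(fit$aic, -2 * fit$loglik + 2 * k)
  expect_equal(fit$bic, -2 * fit$loglik + k * log(fit$n_obs))
})

test_that("a quadratic term is rejected for linear truth, found for thresholds", {
  cmp <- add_quadratic_and_compare(adequacy_spec("enough_staff"),
                                   glmm_fixture$linked)
  expect_gt(cmp$p_quadratic, 0.05)
  expect_gt(cmp$delta_bic, 0)
  expect_identical(cmp$preferred, "linear")

  # a true piecewise logit (no effect until the shortfall passes zero)
  tr <- adequacy_truth()
  tr$enough_staff$threshold_at <- 0
  tr$enough_staff$beta["rn_shortfall_hppd"] <- log(0.45)
  tr$enough_staff$target_rate <- 0.6
  fx2 <- small_linked_study(seed = 202, days = 120, truth = tr)
  cmp2 <- add_quadratic_and_compare(adequacy_spec("enough_staff"),
                                    fx2$linked)
  expect_lt(cmp2$p_quadratic, 0.01)
  expect_identical(cmp2$preferred, "quadratic")
})

test_that("interaction scan flags planted interactions and only those", {
  expect_equal(nrow(interaction_scan(adequacy_spec("enough_staff"),
                                     glmm_fixture$linked, list())), 0)
  # null interaction: non-significant and penalised by BIC
  sc0 <- interaction_scan(
    adequacy_spec("enough_staff"), glmm_fixture$linked,
    list(c("rn_shortfall_hppd", "na_shortfall_hppd"))
  )
  expect_false(sc0$significant)
  expect_gt(sc0$delta_bic, 0)

  tr <- adequacy_truth()
  tr$enough_staff$interactions <- list(
    list(terms = c("rn_shortfall_hppd", "surgical"), beta = 0.5)
  )
  fx3 <- small_linked_study(seed = 203, days = 120, truth = tr)
  sc <- interaction_scan(
    adequacy_spec("enough_staff"), fx3$linked,
    list(c("rn_shortfall_hppd", "surgical"),
         c("rn_shortfall_hppd", "na_shortfall_hppd"))
  )
  expect_true(sc$significant[sc$pair == "rn_shortfall_hppd:surgical"])
  expect_false(
    sc$significant[sc$pair == "rn_shortfall_hppd:na_shortfall_hppd"]
  )
})

test_that("univariable ORs absorb confounding that adjustment removes", {
  # correlated shortfalls, null RN effect, real assistant effect:
  # the one-term model blames the registered nurses
  tr <- adequacy_truth()
  tr$enough_staff$beta["rn_shortfall_hppd"] <- 0
  tr$enough_staff$beta["na_shortfall_hppd"] <- log(0.7)
  fx <- small_linked_study(
    seed = 204, days = 150, truth = tr,
    calibration = calibration_profile(shortfall_cor = 0.7)
  )
  uni <- univariable_or("rn_shortfall_hppd", fx$linked, "enough_staff")
  adj <- fit_adequacy(
    adequacy_spec("enough_staff",
                  fixed = c("rn_shortfall_hppd", "na_shortfall_hppd")),
    fx$linked
  )
  or_u <- uni$coef$or[uni$coef$term == "rn_shortfall_hppd"]
  or_a <- adj$coef$or[adj$coef$term == "rn_shortfall_hppd"]
  expect_lt(or_u, 0.92)            # biased towards the assistant effect
  expect_gt(or_a, or_u + 0.05)     # adjustment moves it back towards 1
  expect_lt(abs(or_a - 1), 0.1)
})

test_that("the shortfall effect curve matches its closed form", {
  spec <- adequacy_spec("enough_staff", quadratic = "rn_shortfall_hppd")
  fit <- fit_adequacy(spec, glmm_fixture$linked)
  grid <- seq(-2, 2, by = 0.5)
  curve <- shortfall_effect_curve(fit, "rn_shortfall_hppd", grid)
  b1 <- fit$coef$estimate[fit$coef$term == "rn_shortfall_hppd"]
  b2 <- fit$coef$estimate[fit$coef$term == "I(rn_shortfall_hppd^2)"]
  expect_equal(curve$odds_ratio, exp(b1 * grid + b2 * grid^2))
  expect_equal(curve$odds_ratio[grid == 0], 1)
  expect_true(all(curve$ci_low <= curve$odds_ratio &
                    curve$odds_ratio <= curve$ci_high))

  # linear-only fit: log-linear curve
  fit_lin <- fit_adequacy(adequacy_spec("enough_staff"), glmm_fixture$linked)
  curve_lin <- shortfall_effect_curve(fit_lin, "rn_shortfall_hppd", grid)
  b <- fit_lin$coef$estimate[fit_lin$coef$term == "rn_shortfall_hppd"]
  expect_equal(curve_lin$odds_ratio, exp(b * grid))
  expect_error(shortfall_effect_curve(fit_lin, "not_a_term"), "fixed term")
})

test_that("excluding a hospital reduces the fit to the remaining ones", {
  spec <- adequacy_spec("enough_staff", exclude_hospital = "A")
  fit <- fit_adequacy(spec, glmm_fixture$linked)
  expect_equal(fit$n_hospitals, 3)
  # excluding all but one drops the hospital level with a warning
  spec2 <- adequacy_spec("enough_staff",
                         exclude_hospital = c("A", "B", "C"))
  expect_warning(fit2 <- fit_adequacy(spec2, glmm_fixture$linked),
                 "hospital-level intercept dropped")
  expect_equal(fit2$n_hospitals, 1)
  expect_identical(fit2$var_hosp, 0)
})
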