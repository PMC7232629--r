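# wardstaff

Nurse staffing requirements from patient acuity censuses: workload
arithmetic for the Safer Nursing Care Tool (SNCT), bootstrap precision
of establishment estimates, and multilevel models of nurse-reported
staffing adequacy.

## What it does, and for whom

Hospitals using a patient classification system rate every ward
patient daily on a five-level acuity/dependency scale; each level
carries a whole-time-equivalent (WTE) multiplier.  For analysts and
workforce teams working with such data, `wardstaff` provides:

* **Workload arithmetic.**  With level counts $n_\ell$, multipliers
  $m_\ell$ and an administrative patient count $N$, the establishment
  estimate is $E = N \sum_\ell n_\ell m_\ell / \sum_\ell n_\ell$ WTE.
  Removing the 22% leave/sickness uplift and converting a 37.5-hour
  week to daily hours gives the implied care requirement
  $h = E/(1+u) \cdot W/7$, from which the package derives hours per
  patient day (HPPD), registered-nurse and assistant shortfalls
  (positive = understaffed), skill mix and turnover per staff hour.
* **Audit precision.**  `bootstrap_establishment()` resamples audits
  of *n* days (1000 resamples, percentile CI) from a unit's daily
  establishment series; `precision_sweep()` tabulates mean CI width
  (WTE), mean precision (half CI width as % of the mean) and the
  number of units estimated within ±0.5 and ±1 WTE, across audit
  lengths 20–180 days.
* **Cleaning rules** for routinely collected unit-day data: first
  assessment of the day (morning, else later), per-unit mean ±3 SD
  extreme-shortfall removal, splitting units at reconfigurations, and
  detection/recoding of units that entered the yes/no adequacy answers
  with inverted 0/1 coding.
* **Adequacy models.**  `fit_adequacy()` fits
  logit P(yes) = xβ + u(unit) + v(hospital) by Laplace-approximated
  maximum likelihood (lme4), reporting odds ratios per natural unit,
  Wald tests, AIC/BIC and variance partition coefficients
  (latent-variable formulation, day residual π²/3).  Quadratic-term
  comparison, interaction scans, univariable ORs, hospital-exclusion
  sensitivity runs and shortfall effect curves are included.
* **A calibrated synthetic generator** (`simulate_study()`): fleets of
  4 hospitals × ~20 units × 365 days whose planted parameters (mean
  multiplier 1.64 ⇒ requirement ≈ 7.2 HPPD and establishment ≈ 35 WTE;
  establishment CV mean 9.4%; shortfalls N(0.1, 0.9) HPPD; adequacy
  odds ratios and VPCs; marginal rates 0.78/0.05/0.05) the pipeline
  must recover — the package's tests are parameter-recovery
  experiments on this generator.

## Worked example

```r
library(wardstaff)

ms <- multiplier_set()   # levels 0/1a/1b/2/3, multipliers 0.99 ... 5.96
counts <- c("0" = 10, "1a" = 5, "1b" = 3, "2" = 2, "3" = 1)
weighted_multiplier(counts, ms)        # 1.519524
establishment_wte(counts, 22, ms)      # 33.42952 WTE to employ
establishment_to_daily_hours(33.43, ms) # 146.79 care hours/day

cfg <- run_config(
  generator = list(config = fleet_config(n_hospitals = 4,
                                         units_per_hospital = 5,
                                         days = 120)),
  outcomes = "enough_staff", sample_sizes = c(20, 40, 60),
  n_boot = 1000, seed = 2025)
res <- run_pipeline(cfg)
res$precision
#>   n_days avg_ci_width_wte avg_precision_pct n_units_width_le_1 n_units_width_le_2 n_units
#> 1     20             2.75              3.79                  0                  6      20
#> 2     40             1.92              2.65                  3                 12      20
#> 3     60             1.57              2.17                  5                 15      20
```

A 20-day audit estimates these units' establishments with a mean 95%
CI width of 2.75 WTE (mean precision 3.8%); only 6 of 20 units are
pinned down to ±1 WTE, and tripling the audit length still leaves a
quarter of units wider than that — establishment estimates from
minimum-length audits are reliable in relative terms but coarse in
absolute staff numbers.

```r
res$fits$enough_staff$adjusted
#> Three-level staffing-adequacy model: outcome enough_staff
#>   2024 days in 20 units in 4 hospital(s); 370 dropped
#>                 term estimate     se      z       p     or  ci_low ci_high
#> 2  rn_shortfall_hppd  0.04946 0.0954  0.518 0.60430 1.0507 0.87144    1.27
#> 3  na_shortfall_hppd -0.09468 0.1106 -0.856 0.39175 0.9097 0.73244    1.13
#> 5           surgical -1.48892 0.5474 -2.720 0.00653 0.2256 0.07717    0.66
#>   ...
#>   var(unit) = 1.244  var(hospital) = 0.349  VPC 0.255 / 0.071
#>   AIC 1631.1  BIC 1709.7  converged: TRUE
```

Each row is an adjusted odds ratio per natural unit — e.g. per one
HPPD of registered-nurse shortfall — for reporting "enough staff to
provide quality care"; `or_to_percent_change(0.89)` expresses such an
OR as a −11% change in odds.  (This small 20-unit example is too noisy
to pin the shortfall effects down; the full-scale recovery experiments
live in the test suite.)  VPCs say what share of latent outcome
variance sits between units and between hospitals.

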