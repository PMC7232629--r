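---
title: "Estimating ward nurse staffing requirements and their precision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ward nurse staffing requirements and their precision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardstaff)
```

## The problem

Acute hospitals must decide how many nurses to employ on each ward (the
*establishment*) and how many to deploy each day.  The Safer Nursing
Care Tool (SNCT) is the patient classification system most widely used
in the English NHS for this purpose: at least once a day the nurse in
charge assigns every occupied bed to one of five acuity/dependency
levels, each carrying a multiplier expressing the whole-time-equivalent
(WTE) staffing that such a patient requires.  `wardstaff` implements
the full analysis pipeline around that calculation:

1. **Workload arithmetic** (`weighted_multiplier()`,
   `establishment_wte()`, `compute_workload()`): from a day's census to
   establishment WTE, required daily care hours, the registered
   nurse / nursing assistant split, hours per patient day (HPPD),
   signed staffing shortfalls and patient turnover.
2. **Audit precision** (`bootstrap_establishment()`,
   `precision_sweep()`): how precisely a unit's establishment is
   estimated from an audit of *n* days, by bootstrap resampling.
3. **Cleaning rules** (`select_daily_assessment()`,
   `remove_shortfall_outliers()`, `split_units_on_change()`,
   `detect_and_recode_reverse_coding()`, `link_days()`): the rules
   needed to turn routinely collected unit-day records into an
   analysable table.
4. **Adequacy models** (`fit_adequacy()` and friends): three-level
   logistic regressions of nurse-reported staffing adequacy on
   staffing shortfalls, with days nested in units nested in hospitals.
5. **A calibrated synthetic generator** (`simulate_study()`): fleets
   of hospitals/units/days with known planted parameters, used to
   validate every stage by parameter recovery.

## The staffing model

For a census with $n_\ell$ patients at level $\ell$ and level
multipliers $m_\ell$ (defaults $0.99, 1.39, 1.72, 1.97, 5.96$ for
levels 0, 1a, 1b, 2, 3), the weighted average multiplier is
$\bar m = \sum_\ell n_\ell m_\ell / \sum_\ell n_\ell$.  Multiplying by
the patient count $N$ taken from the administration system (used
deliberately, in case the shift leader's report omits patients) gives
the establishment estimate $E = \bar m N$ in WTE.  The establishment
includes a 22% *uplift* for annual leave, study time and sickness, so
the daily care hours it can supply are

$$h = \frac{E}{1 + u} \cdot \frac{W}{7}, \qquad u = 0.22,\; W = 37.5
\text{ h/week},$$

i.e. division by $1+u$, because the uplift is added on top of the base
requirement.  One-to-one ("specialing") patients add 24 h per
patient-day to the *daily* requirement but not to establishment
estimates, whose multipliers already average over enhanced care.
Required hours are split between registered nurses and assistants by
the unit's average observed skill mix, which stands proxy for the
planned mix.  The signed shortfall for a day is
$(\text{required} - \text{deployed})/(\text{patient-hours}/24)$, in
hours per patient day: positive when understaffed.

## Precision of establishment estimates

A staffing audit observes $n$ days (the recommended minimum baseline is
20) and averages the daily establishment estimates.
`bootstrap_establishment()` draws 1000 resamples of size $n$ with
replacement from a unit's daily series, takes the 2.5% and 97.5%
quantiles of the resample means (percentile CI; a normal-approximation
CI is available via `method = "normal"`), and reports *precision* =
half the CI width as a percentage of the mean.  Resampling treats days
as exchangeable; no block bootstrap is attempted, matching how audit
days are actually sampled.  A unit whose series is shorter than $n$ is
ineligible for that audit length and is excluded from that row of
`precision_sweep()`, not an error.  The precision of a zero-mean
series is undefined and reported as missing.

## The adequacy models

Every morning the shift leader answers three yes/no questions about
the previous 24 h: were there enough staff to provide quality care,
was necessary care left undone, were staff breaks missed.
`fit_adequacy()` models each answer with a logistic mixed model,

$$\operatorname{logit} P(y_{ijk} = 1) = \mathbf{x}_{ijk}^\top \beta +
u_{jk} + v_k, \quad u_{jk} \sim N(0, \sigma^2_u),\;
v_k \sim N(0, \sigma^2_v),$$

for day $i$ in unit $j$ in hospital $k$, fitted by maximum likelihood
with the Laplace approximation (`lme4::glmer`; with two nested random
intercepts lme4 supports exactly this approximation, so no adaptive
quadrature upgrade is attempted — equivalence is asserted at the level
of recovered parameters, not likelihood values).  Covariates enter in
natural units (per HPPD of shortfall, per unit of proportion), so odds
ratios are directly interpretable; day of week uses Monday as
reference; standard errors and p-values are Wald z-tests.  Days with a
missing outcome or covariate are deleted listwise and counted.
Degenerate outcomes and complete separation on a categorical covariate
are errors; non-convergence is flagged on the result, never silent.

Variance partition coefficients use the latent-variable formulation
with day-level residual variance $\pi^2/3$, each level's variance
divided by the *same* total
$\sigma^2_u + \sigma^2_v + \pi^2/3$ (non-cumulative).  This is an
interpretation choice: it is the unique convention under which a
variance pair maps one-to-one to a VPC pair, e.g.
$(\sigma^2_u, \sigma^2_v) = (1.097, 0.598) \mapsto (0.220, 0.120)$,
and `vpc_to_variances()` inverts it exactly.  AIC and BIC count fixed
effects plus the two variances, with $n$ = day-level observations for
BIC.  Quadratic shortfall terms and interaction pairs are compared by
AIC and BIC jointly; when the two criteria disagree the comparison is
reported `"ambiguous"` rather than forced.

## What the synthetic generator emulates

`simulate_study()` generates the study frame the analysis assumes:
4 hospitals, ~20 general medical/surgical units each, 365 days.  Its
defaults are the study conditions, chosen once:

* **Beds** $20 + \mathrm{Bin}(16, 7/16)$ (range 20–36, mean 27) and
  occupancy 0.79, so the mean daily census is ≈21.3 patients and a
  fleet of ~80 units carries ≈2160 beds.
* **Case mix**: each unit draws a mean multiplier
  $m_u \sim N(1.64, 0.12)$ (clamped to $[1.2, 2.4]$).  At the default
  uplift and working week, $\bar m = 1.64$ implies a care requirement
  of $1.64 \times 37.5/(7 \times 1.22) \approx 7.2$ HPPD and a mean
  establishment of $1.64 \times 21.3 \approx 35$ WTE.
* **Day-to-day variation**: each unit draws an establishment
  coefficient of variation from a Gamma distribution with mean 9.4%
  (SD 0.045, clamped to $[0.01, 0.30]$), split 36% census-size /
  64% case-mix on the variance scale.  A CV of 9.4% is what makes a
  20-day audit's precision average ≈
  $1.96 \times 9.4/\sqrt{20} \approx 4.1\%$ and its CI width ≈
  $2 \times 1.96 \times 0.094 \times 35/\sqrt{20} \approx 2.9$ WTE.
  Integer patient counts are produced by largest-remainder rounding of
  an interpolated level composition followed by greedy single-patient
  moves toward the day's target multiplier, and the census lognormal
  is shrunk by the $1/12$ integer-rounding variance — without these
  corrections rounding noise inflates the realised CV well above the
  planted one (an iid multinomial census would add ~15% CV on its own
  through the rare heavy level-3 multiplier, which is why the
  generator pins compositions instead of drawing them per patient;
  real censuses persist across days and are far less dispersed than
  iid multinomial).
* **Rosters**: deployed hours equal the day's requirement (including
  Poisson(0.15) specialing patients) minus a Normal(0.1, 0.9) HPPD
  total shortfall, split RN/assistant by the unit's planned skill mix
  (mean 0.56) with independent group draws (`shortfall_cor` makes
  them correlated for confounding experiments); hours are floored at
  zero.  Poisson(3.1) admissions and discharges give turnover ≈0.04
  patients per staff hour.
* **Outcomes**: the three answers are drawn from the three-level
  logistic model with planted log odds ratios (RN shortfall 0.89,
  assistant 0.86 on enough-staff; 1.14/1.14 and 1.12/1.11 on the two
  care-omission outcomes; surgical 0.54, etc.), variances derived from
  target VPC pairs, and intercepts solved numerically so the marginal
  rates are 0.78 / 0.05 / 0.05.  Random intercepts are centred and
  rescaled so the *realised* between-group variances equal the planted
  ones exactly (with only 4 hospitals, an unstandardised draw would
  make the hospital variance essentially arbitrary); outcomes are
  independent given the linear predictor, so cross-outcome correlation
  is not modelled.
* **Contamination**: `inject_missingness()` thins morning assessments
  to ~96% and responses to ~85%; `inject_reverse_coding()` inverts all
  three answers for chosen units.  Ground truth is attached to the
  returned objects so cleaning tests are self-verifying.

What passing recovery tests on this generator shows is that the
pipeline estimates *without bias at realistic scale and noise* the
parameters of the process it assumes; it cannot show robustness to
features the generator omits (serial correlation of censuses,
outcome-dependent missingness, cross-outcome correlation, seasonal
demand, real reverse-coding patterns more subtle than full inversion).

## Cleaning rules

Extreme-shortfall days are removed per unit at mean ±3 SD (a pooled
option exists); with SD 0 nothing is removed.  Units are split into
derived units at dated reconfiguration events, dropping segments under
28 days (too short for even the minimum 20-day audit analyses).
Reverse-coded units are detected from *marginal-rate reversals*: a
unit is flagged when at least two of the three answers sit on the
opposite side of 0.5 from the fleet median (enough-staff below,
care-undone and breaks-missed above).  Consistent inversion of all
three answers leaves every between-answer correlation unchanged, so
association signs cannot identify it, and at the planted effect sizes
shortfall–answer associations are too weak (|r| ≈ 0.05) for reliable
sign tests on a year of data; the rate rule separates inverted units
essentially completely while leaving honestly low-adequacy units
(low enough-staff rate but ordinary care-omission rates) unflagged.
The shortfall association is still computed per unit as a logged
diagnostic.  Flagged units have all three answers inverted back;
detection after recoding flags nothing (involution).

## Numerical and design choices

* Percentile bootstrap quantiles interpolate linearly between order
  statistics (R quantile type 7).
* Every stochastic stage takes a seed derived from the master seed by
  `derive_seed()` (affine-modular, always < 2^31), so any stage or any
  single bootstrap cell reproduces in isolation; fixed seeds make all
  generator output bit-identical.
* Intercept solving uses `uniroot` on the realised mean response
  probability (tolerance 1e-10), conditioning on the realised random
  effects and covariates.
* Test problem sizes: unit tests use fleets of 12–40 units over
  80–150 days; recovery properties use 20 replicates of a
  4 × 5 × 90-day fleet; end-to-end calibration checks use the
  full default frame (80–86 units × 365 days).  These sizes were
  chosen so each suite exercises the asymptotics it relies on.
* `total_shortfall_hppd` and the RN/assistant pair are mutually
  exclusive model terms (the former is the latter's sum); the
  total-hours + skill-mix parameterisation is available through
  `adequacy_spec(fixed = c("total_shortfall_hppd", "skill_mix", ...))`.
* Whether daily specialing requirements belong to the registered-nurse
  or assistant side is not identified by the source data description;
  they are split by the unit's planned skill mix, and both the hours
  per specialed patient (24) and the split are configuration keys.

## Known limitations

* With four hospitals the hospital-level variance is intrinsically
  ill-determined; the generator standardises realised effects so
  recovery is testable, but on real data the hospital VPC should be
  read qualitatively.
* The bootstrap ignores serial correlation in censuses; if real
  demand is autocorrelated, audit precision at a given $n$ will be
  optimistic.
* The reverse-coding detector assumes inversion of all three answers
  at once and year-scale data; partial or intermittent miscoding needs
  different rules.
* Odds ratios for turnover are reported per whole unit of patients per
  staff hour while its observed range is ~0.02–0.08, so its CI is
  inevitably wide; this matches how the covariate is defined, not a
  numerical problem.
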