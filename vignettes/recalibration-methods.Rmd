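---
title: "Methods: competing-risks recalibration of 10-year fatal-CVD risk charts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competing-risks recalibration of 10-year fatal-CVD risk charts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdrecal)
```

## The model

The package computes an individual's absolute 10-year risk of fatal
cardiovascular disease (CVD) by recalibrating an externally estimated
relative-risk model to national mortality and risk-factor levels. Death
from non-CVD causes is a competing event: a person who dies of something
else can no longer die of CVD, so the quantity of interest is the
cumulative incidence function (CIF) of CVD death, not the naive
`1 − exp(−cumulative hazard)`.

Three inputs drive the computation.

* **Cause-specific mortality rates.** National death counts and population
  denominators by sex and 5-year age band give annual rates
  `m_cvd(b)` and `m_noncvd(b)` per band `b`. These are the baseline
  hazards of an average person in that band.
* **Log hazard ratios** `β` for systolic blood pressure (per mmHg),
  cholesterol (per mmol/L of total cholesterol, or per unit of the
  TC/HDL-C ratio — two interchangeable chart versions), and current
  smoking. They come from an external proportional-hazards analysis of
  pooled cohort data and are supplied as configuration with a provenance
  string; the package deliberately ships no numeric values for them.
* **Population mean risk-factor levels** `x̄(sex, b)`: mean SBP, mean TC,
  mean TC/HDL-C and smoking prevalence per sex and band, estimated from a
  national examination survey with survey weights (the saturated model in
  5-year age groups, i.e. weighted means within sex × band cells —
  `estimate_means()`).

An individual with factor vector `x` has, in band `b`,

$$\mathrm{HR}(x, b) = \exp\{\beta'(x - \bar x(b))\},$$

with smoking coded as the 0/1 indicator minus the band's smoking
prevalence, so that a person exactly at the band means has HR = 1 by
construction. The band's hazards for that person are
`h_cvd = m_cvd(b) · HR(x, b)` and `h_noncvd = m_noncvd(b)`; the competing
hazard is never modified by risk factors, because the relative risks were
estimated for CVD mortality only.

The 10-year horizon `[a, a+10)` is partitioned along the 5-year grid —
two 5-year pieces for chart-aligned entry ages, three pieces summing to 10
years otherwise — and the CIF is chained with constant hazards per piece:

$$R = \sum_b S(t_b)\,\frac{h_{cvd,b}}{h_b}\left(1 - e^{-h_b\Delta_b}\right),
\qquad S(t_b) = \prod_{b'<b} e^{-h_{b'}\Delta_{b'}}.$$

By the same chaining, `CIF_cvd + CIF_noncvd + S(10) = 1` to machine
precision — a conservation identity the test suite checks at tolerance
1e−12.

### The "mean-person" calibration

The observed band rate is assigned to the person standing at the band's
mean factor levels, and everyone else is scaled by their HR relative to
that person. A stricter alternative would normalise by the population
mean hazard ratio, `E[HR]`, which requires individual-level national
covariate data that calibration settings typically lack. The mean-person
form is the established convention for this chart family, is reproducible
from published aggregate tables alone, and is what this package
implements.

### Constant vs interpolated rates

Holding rates constant within bands is what the Markov assumption —
transition intensities depend only on the current age band — implies.
The older chart generation instead interpolated the 5-year rates across
age. That method survives here as `ten_year_risk_interpolated()`, used
for sensitivity comparison: annual cause-specific rates are anchored at
band midpoints (`start + 2.5`), joined linearly in age and extrapolated
as constants beyond the outermost midpoints; the horizon is walked in
1-year steps with rates evaluated at each step midpoint, the HR taken
from the band containing that midpoint, and the same CIF chaining
applied. The midpoint-linear choice is a design decision (the precise
historical interpolation is not documented); it was chosen because it
makes the flat-rate limit exact: when all bands share the same rates,
interpolation returns those constants and the two methods agree to
floating-point error, which the suite checks at 1e−9.

Chart comparison (`compare_charts()`) matches cells on sex, smoking,
entry age, SBP and cholesterol, counts higher/lower/equal cells on the
rounded display values (the chart reader's view), reports the mean and SD
of absolute raw cell differences in percentage points, and computes the
intraclass correlation of the paired raw risks. The ICC variant is fixed
to ICC(A,1) — two-way random effects, absolute agreement, single
measurement — since "agreement between two methods measuring the same
cells once each" is exactly that design. Legacy grids with a single
40–49 band can be matched one-to-many to modern 40–44 and 45–49 bands via
the `age_map` hook.

## Display and rounding conventions

Cells display `round(100 · risk)` with half-away-from-zero rounding
(`round_half_away`), values below 0.5% printing as `"<1"`, and colour
bins `<1, 1, 2, 3–4, 5–9, 10–14, ≥15` percent. In higher/lower/equal
counts a `"<1"` cell is treated as display value 0, i.e. two sub-0.5%
cells tie. Raw risks are always preserved in the chart CSV; comparisons
on raw values are available with `on = "raw"`.

Chart reading rounds a person's age to the nearest chart age (ties round
up, `nearest_chart_age()`); cohort application deliberately does *not*
round — `apply_risk()` evaluates the formula at the exact recorded age
through the three-band horizon partition, which is the higher-precision
"direct formula" route.

## Rates as hazards

Annual rates are used directly as hazards (`m ≈ h`). For the rates this
method is meant for (< 0.05/year) the difference from the exact
conversion `h = −log(1 − m)` is far below chart rounding resolution; a
`strict_hazard` switch applies the exact conversion for users who want
it, and a test pins the relationship (strict is slightly larger, equal to
the closed form).

## Survey-weighted estimation

`weighted_mean_risk()` and `weighted_high_risk_prevalence()` compute
Hájek (ratio) estimators `Σwy / Σw` with Taylor-linearized standard
errors treating weights as given,
`var = n/(n−1) · Σ (w_i(y_i − ŷ)/W)²`, and normal-approximation
confidence intervals truncated to [0, 1]. Stratum and cluster structure
is out of scope: full design-based variance needs survey-design metadata
that the supported CSV schema does not carry, and the linearized form is
directly testable against a weighted bootstrap (the suite requires
agreement within 10% of a 2000-replicate bootstrap SE). Estimates are
exactly invariant to rescaling all weights by a constant. The high-risk
threshold defaults to 0.05 and is inclusive ("5% or more").

The eligibility cascade in `filter_cohort()` is sequential and
order-fixed: missing data first (any risk variable or prior-CVD flag),
then history of major CVD (coronary heart disease, stroke or heart
failure), then age outside [40, 65]. A record failing several rules is
counted once, at the first failing step — the accounting convention of
survey exclusion flowcharts.

## What the synthetic generators emulate

`sim_params()` fixes the study conditions for all generators:

* **Mortality**: Gompertz cause-specific rates
  `m(a) = m₀·exp(γ(a−40))·sexmult`, evaluated at band midpoints (the
  midpoint value, not the band-average integral, defines the band — the
  simpler choice, consistent with the piecewise-constant model). Defaults
  `m₀_cvd = 5·10⁻⁴`, `γ_cvd = 0.09`, `m₀_noncvd = 1.5·10⁻³`,
  `γ_noncvd = 0.085`, female multipliers 0.55/0.65 — an
  order-of-magnitude match to contemporary western European mortality
  that places chart cells in the realistic 0–30% range. Deterministic
  (expected-count) mode is the test default; Poisson counts are available
  for robustness checks.
* **Survey records**: uniform ages over [38, 75] (so both the age filter
  and the outermost band means are exercised), normal SBP and TC with
  linear age trends (120/127 mmHg at 40, +0.5 mmHg/y, SD 16; 5.2/5.5
  mmol/L, +0.015/y, SD 1.0), truncated-normal HDL (> 0.3 mmol/L),
  Bernoulli smoking (24%/30%), log-normal weights (sdlog 0.5), and
  planted defects: prior-CVD flags at 5.1% (women) / 10.9% (men) and a
  3.8% missingness rate — the exclusion fractions typical of a national
  examination survey of this age range. The generator returns its planted
  disposition labels so filter tallies are testable against ground truth.
* **The Monte-Carlo oracle** (`simulate_deaths()`): n individuals walked
  through the piecewise-constant two-cause exponential model; per band,
  competing event times are drawn, the earliest within the band wins,
  survivors advance. The CVD-death fraction and its binomial SE provide
  an implementation-independent check of the analytic CIF; the suite and
  the acceptance script require agreement within 4 binomial SEs across 20
  seeded parameter draws at n = 2·10⁵.

What the generators do **not** emulate: multi-stage cluster sampling and
nonresponse models (weights are iid log-normal, so passing tests say
nothing about design-based variance), measurement error in blood pressure
or lipids, secular trends within the survey period, correlation between
risk factors, and the selection effect of prior-CVD cases on national
mortality rates. Passing the recovery tests demonstrates internal
consistency of the estimator chain, not fidelity to any real country's
data.

## Numerical choices

* Floating comparisons default to absolute tolerance 1e−12; the
  flat-limit method equivalence is asserted at 1e−9 (ten chained
  exponentials), the band-mean/population-CIF identity at 1e−10.
* `cif_band()` returns 0 exactly when both hazards are zero (the 0/0
  limit), so "risk = 0 iff every band's CVD hazard is 0" holds exactly.
* Age ties in chart rounding round toward the older age; the horizon
  partition uses half-open `[age, age+10)` intervals, so a 65-year-old
  needs bands 65–69 and 70–74, which is why tables must cover [40, 75).
* The ICC denominator can be non-positive only when the data are constant
  (defined as 1 under exact agreement, an error otherwise) or in
  adversarial zero-variance arrangements (an error); a pure rater offset
  with no between-cell variance yields ICC = 0, the correct value.
* HDL truncation resamples rather than clamps, preserving the normal
  shape above the bound; resampling is seed-deterministic.

## Problem sizes

The test suite runs the Monte-Carlo oracle at n = 2·10⁵ per draw (20
draws), mean-recovery at n = 50,000 survey records, bootstrap SE checks
at 2,000 replicates on cohorts of ~1,500, and chart work on full
480-cell grids — sizes at which binomial and normal-theory error bands
are tight enough for 3–4 SE assertions to be meaningful while the whole
suite stays interactive.

## Known limitations

* The competing-risk correction applies to the baseline only; the hazard
  ratios themselves come from a cause-specific proportional-hazards
  analysis, not a subdistribution (Fine–Gray) model. Re-estimating
  subdistribution coefficients is out of scope.
* National mortality includes people with prevalent CVD, so the baseline
  overstates the risk of the CVD-free chart population; correcting this
  requires incidence data the method does not assume.
* Charts and the engine are restricted to ages 40–65 at entry (bands
  through 70–74 internally) and to fatal CVD as the endpoint.
* Separate coronary and stroke endpoints, and re-fitting of the
  relative-risk model from cohort microdata, are intentionally not
  implemented.
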