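---
title: "Temperature-driven phenology models and pest risk indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature-driven phenology models and pest risk indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenrisk)
```

## The model

`phenrisk` implements process-based, temperature-driven phenology
modelling for insect pests, in the tradition of life-cycle modelling
tools used for tephritid fruit flies. A phenology model is a set of
temperature response functions, one per life-history process:

* **Development rate** per immature stage (egg, larva, pupa): the
  Briere-1 curve \(r(T) = a\,T\,(T - T_{min})\sqrt{T_{max} - T}\),
  clamped to zero outside \((T_{min}, T_{max})\). Its maximum has the
  closed form
  \(T_{opt} = \frac{1}{10}\big(4T_{max} + 3T_{min} +
  \sqrt{16T_{max}^2 + 9T_{min}^2 - 16T_{min}T_{max}}\big)\).
  A linear regression \(r(T) = a + bT\) over the sub-optimal range
  provides the conventional lower development threshold \(-a/b\).
* **Development-time variability**: development times at different
  temperatures are assumed to share one distributional shape. On the
  log-time scale this is the logit model
  \(F(x) = 1/(1 + e^{-(a_i + b\ln x)})\) with a per-temperature
  intercept \(a_i\) and a common slope \(b\); the median time at
  temperature \(i\) is \(e^{-a_i/b}\).
* **Immature mortality** per stage: \(M(T) = \exp(b_1 + b_2T + b_3T^2)\),
  clipped to \([0,1]\); with \(b_3 > 0\) it is U-shaped with minimum at
  \(-b_2/(2b_3)\). Lethal temperatures (the crossings of a given
  mortality level, e.g. LT50) are recovered by bisection on
  \([-20, 60]\,^\circ\)C to \(10^{-6}\,^\circ\)C, or in closed form for
  the clipping boundary.
* **Adult senescence**: the aging rate \(s(T)\), either exponential
  \(b_1 e^{b_2 T}\) or the modified four-parameter Stinner double
  logistic. Expected longevity at constant temperature is \(1/s(T)\).
* **Reproduction**: lifetime eggs per female \(f(T)\)
  (exponential-polynomial or Gaussian), and a cumulative oviposition
  curve \(O(x)\) over *normalized female age* \(x\) — age divided by
  mean survival time, equivalently accumulated senescence — in one of
  three families (cubic-exponential, logistic, gamma CDF).

All forms are first-class `thermal_spec` objects that serialize to flat
key-value lists (JSON), and `fit_response()` estimates any of them from
tabular observations by Levenberg–Marquardt least squares with a
deterministic multi-start grid. Model choice uses the Gaussian
least-squares AIC, \(n\ln(RSS/n) + 2k\), with ties broken by higher
\(R^2\) and then fewer parameters. The female sex ratio is fixed at 0.5
throughout, exposed as a model field.

## Stochastic cohort simulation

`simulate_cohort()` advances a cohort of eggs day by day under a daily
minimum/maximum temperature series:

* **Rate summation.** Within each day, temperature follows a cosine
  cycle between the day's minimum and maximum (24 steps by default, the
  standard degree-day practice); stage development accumulates the mean
  of \(r(T_h)\) over the cycle. The daily mean of the cosine cycle is
  exactly \((t_{min}+t_{max})/2\) and both extremes are attained.
* **Cohort updating.** Each individual draws a stage threshold
  \(q = \exp(\mathrm{logit}(u)/b)\) at stage entry — the median-1
  log-logistic quantile implied by the development-time slope \(b\) — and
  completes the stage when accumulated development reaches \(q\).
  Mortality is apportioned by development fraction: the daily death
  probability is \(1 - (1 - M(\bar T_d))^{\Delta}\), where \(\Delta\) is
  the fraction of the individual's stage requirement completed that day
  (including partial entry days, so the exponents sum to exactly 1).
  This is the only allocation under which whole-stage survival at
  constant temperature equals \(1 - M(T)\), which is how whole-stage
  mortality curves are measured.
* **Adults.** Sex is assigned with probability 0.5 (drawn at cohort
  initialization; survival is sex-independent, so this is equivalent to
  assignment at emergence while keeping the female survivorship curve
  monotone). A female's normalized age accumulates \(s(T)\); she lays
  \(f(\bar T_d)\,[O(x_{end}) - O(x_{start})]\) eggs per day and dies
  when \(x\) reaches her senescence threshold — exactly 1 under the
  default deterministic `adult_slope = Inf`, or a log-logistic draw for
  finite slopes. Males age identically without reproducing and are
  excluded from the life table.

Because death occurs at \(x = 1\) and \(O(1) < 1\) for realistic
oviposition curves, a simulated female lays \(f(T)\,[O(1) - O(0)]\) eggs
in total. When a model is *fitted* from observed lifetime totals,
`fit_phenology_model()` rescales the fecundity curve by the fitted
\(1/[O(1)-O(0)]\) so the compiled model reproduces the observed totals in
simulation — without this, fitting and simulating would silently lose
the un-laid tail of the oviposition curve.

### Life-table parameters

From 50 repetitions (the default study design: 100 individuals each),
`estimate_life_table_parameters()` computes per repetition:
\(R_0 = \sum_x l_x m_x\); \(r_m\) solving the Euler–Lotka equation
\(\sum_x e^{-r_m(x + 0.5)} l_x m_x = 1\) by bisection (tolerance
\(10^{-10}\), bracket \([-1, 2]\) per day, auto-expanded for extreme
schedules); \(\lambda = e^{r_m}\); \(T = \ln R_0 / r_m\);
\(D_t = \ln 2 / r_m\). These identities hold *exactly* for every
repetition by construction. A repetition with \(R_0 \le 1\) yields
\(r_m \le 0\) honestly; \(R_0 = 1\) yields \(r_m = 0\) with an infinite
doubling-time sentinel; cohorts with no reproduction at all are flagged
non-viable rather than propagating NaN.

Gross reproduction (GRR) is estimated directly as female eggs per adult
female. The naive sum of the realized \(m_x\) schedule is biased upward
in small staggered cohorts — late egg increments are divided by the few
females still alive — by ~40% at \(n = 100\); the direct estimator is
unbiased for the same quantity and matches the deterministic
expected-cohort value exactly.

`expected_cohort_parameters()` provides the independent deterministic
check used throughout the tests: at constant temperature,
\(R_0 = \prod_s(1 - M_s)\cdot f(T)\,E[O(s^\ast)]\cdot\phi\) in closed
form. The stochastic and deterministic routes share no simulation code.

## Risk indices

Given a phenology model and one year of daily temperatures:

* **ERI** (establishment risk index): the fraction of days on which all
  three immature stages have positive survival
  (\(M(\bar T) < 1\)) at the daily mean temperature. The published
  definition carries an ambiguous reproduction superscript; the
  implementation defaults to the immature-survival reading — matching
  the stated boundary behaviour that the index is 1 when all immature
  stages survive year-round — with `require_reproduction = TRUE`
  additionally demanding \(f(\bar T) > 0\).
* **GI** (generation index): \(\frac{1}{365}\sum_x 365/T_x\), where
  \(T_x\) is the generation length starting at Julian day \(x\): a
  deterministic median-individual forward run (egg, larva and pupa each
  accumulating one development unit by rate summation, then the adult
  female reaching the age of 50% cumulative oviposition), the year
  cycled as needed, capped at 5 years. The exact reference definition of
  the generation endpoint is not published; the 50%-oviposition age is
  this package's documented choice. Start days that never complete
  contribute 0.
* **AI** (activity index): \(\sum_x \log_{10} \lambda(\bar T_x)\), with
  \(\lambda\) evaluated from the quadratic trend fitted to the
  simulated finite rates of increase across temperature (the package
  fits all life-table parameters to quadratics, matching practice) and
  floored at 0.5/day outside the viable range so the index is bounded
  below instead of diverging. Each unit of AI is a 10-fold annual
  multiplication; AI = 3 is a 1000-fold increase.

`compute_indices_for_grid()` applies all three per cell over 12 monthly
minimum and maximum rasters, interpolating monthly values to 365 daily
values linearly between month midpoints (wrapped across the year
boundary; the reference work does not state its temporal downscaling).
Nodata propagates. Grid I/O is the ESRI ASCII dialect with a full
round-trip guarantee. `classify_establishment()` exports the
conventional binary layer at a configurable ERI cutoff (default 0.6).

## The synthetic-data generator

The raw rearing observations behind the published parameter tables are
not deposited, so `generator_config()` + the `generate_*()` functions
reproduce the *design* of the original study as defaults: seven constant
temperatures (10, 15, 20, 25, 30, 33, 35 °C), cohorts of 100 replicated
five times per stage, 15 adult pairs per temperature, and an
outdoor-like fluctuating year whose daily minima span 9.14–16.68 °C and
maxima 18.84–37.66 °C. Survival is Binomial in \(1 - M(T)\), durations
are log-logistic with median \(1/r(T)\) (the same distribution the
development-time model assumes), and daily egg counts are Poisson around
\(f(T)\,\Delta O\) — the minimal noise model; the generator does not
emulate overdispersed fecundity, humidity or host-plant effects,
between-replicate batch effects, or real spatial autocorrelation in the
climatology. Passing tests therefore demonstrate internal correctness
and recoverability under the assumed noise structure, not robustness to
the messiness of real rearing data.

`reference_model()` packages two compiled fixtures ("rosa", lowland
type; "quilicii", highland type) whose mortality, senescence, fecundity
and oviposition parameters are the published estimates verbatim, also
shipped as JSON under `inst/extdata/` (filenames flag the synthetic
development rates).

## Design decisions on ambiguous points

* **Mortality scale.** Taken as printed proportions, the published
  larval and pupal mortality parameters imply \(M(T) \ge 1\) at *every*
  temperature for both species (e.g. the lowland larval curve has
  minimum \(e^{3.9} \approx 50\)) — certain death everywhere, which
  contradicts the same study's observed survival and thriving simulated
  populations. `eval_mortality()` is therefore scale-free by default
  (proportion semantics), and the packaged fixtures carry an explicit
  `scale = "percent"` field under which the printed parameters yield
  usable survival (the lowland fixture is viable at roughly 20–33 °C).
  The published narrative LT50/LT100 values are not reproducible from
  the printed parameters under either scale and are not asserted
  anywhere.
* **Fixture development rates.** Briere-1 parameters for these species
  are not published (cited to earlier work); the fixtures use synthetic
  values scaled so stage durations at favourable temperatures match the
  reported ~2.3/9.1/11.9 days, and are flagged as synthetic in the
  fixture filenames and documentation. Development-time slopes (8) and
  the deterministic adult threshold are likewise package choices.
* **Published life-table tables.** The published per-temperature
  (\(r_m, \lambda, D_t, T\)) triples violate the standard identities
  (\(\lambda \ne e^{r_m}\) etc.), so they cannot be an exact numerical
  target; this package enforces the identities and asserts only the
  qualitative result that the fitted quadratic peaks in the favourable
  25–30 °C range.
* **Development-time inference.** The common-slope logit is fitted as a
  single binomial regression on cumulative completion counts pooled
  over temperatures (not per-temperature fits averaged), which encodes
  the same-shape assumption directly. Because cumulative counts are
  serially correlated, the model-based standard errors of that GLM are
  not valid sampling errors; the slope estimate itself is accurate
  (within 15% at \(n = 100\) per temperature in simulation), and tests
  judge it at that tolerance.

## Numerical choices and problem sizes

Cosine rate summation uses 24 steps/day. Euler–Lotka bisection:
tolerance \(10^{-10}\), 200 iterations max. Generation-length crossings
are solved on cumulative daily rate sums with within-day linear
interpolation, vectorized over start days. Nonlinear fits run from
deterministic start grids (Briere thresholds initialized just outside
the observed temperature range; log-linear regressions seed the
exponential families); convergence is reported honestly and
non-converged fits are excluded from model selection. The test-suite
and analysis scripts use the study-design sizes throughout — 100
individuals × 50 repetitions per temperature, 7 temperatures — and
20×20 synthetic rasters for the grid equivalence checks; the packaged
analysis climatology is 12×10 at 0.5° resolution.

## Known limitations

No density dependence, host effects, humidity or photoperiod
covariates, dispersal, or interspecific competition; no bootstrap or
Bayesian uncertainty on fitted curves (only Wald standard errors); the
highland fixture's pupal mortality parameters are garbled as published
(quadratic coefficient orders of magnitude out of range) and render
that fixture non-viable at all temperatures — it is still shipped
verbatim, and the lowland fixture is the working example.
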