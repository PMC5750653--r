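---
title: "Weight-metric dosing simulations for FVIII prophylaxis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weight-metric dosing simulations for FVIII prophylaxis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific content of `fviiidose`: the models
it implements, the assumptions behind them, the tunable parameters and
their defaults, and the numerical and design choices that were genuinely
open. The package's question is operational: for adult hemophilia A
prophylaxis with a conventional factor VIII (FVIII) concentrate, what is
the minimal dose — written per kilogram of total, lean, ideal or adjusted
body weight — that keeps the steady-state weekly trough activity at or
above 1 IU/dL in at least 95 % of a simulated population, and what does
each choice of weight metric cost in weekly factor consumption?

## The virtual population

```{r, eval = FALSE}
library(fviiidose)
pop <- generate_population(population_spec(n_per_group = 1000, seed = 1))
summarize_population(pop)
```

Two cohorts of adult males are generated (hemophilia A is X-linked, so
only male anthropometric formulas are carried):

* **normal BMI**: uniform on [20.3, 29.6) kg·m⁻²;
* **overweight/obese**: uniform on [29.6, 40.0) kg·m⁻².

The bin edges are the BMI cut-points that best predict in vivo recovery
differences in adults; bins are half-open so the shared 29.6 boundary is
unambiguous. Heights are drawn i.i.d. from a normal distribution with
mean 175.7 cm and SD 7.4 cm, truncated to [150, 200] cm, and
independently of BMI. These values represent NHANES adult males; the
source study cites the NHANES height distribution without parameters, so
mean, SD and truncation bounds are exposed in `population_spec()` and
`study_config()` so that sensitivity to this choice can be examined.
Total body weight is computed exactly as TBW = BMI × (HT/100)², which
makes BMI uniform *by construction* and concentrates all weight
variability at fixed BMI into height.

What the generator deliberately does **not** emulate: joint
height–weight structure of real cohorts (real BMI is not uniform and not
independent of height), females, children, and secular/regional height
differences. Passing tests therefore demonstrate correctness of the
simulation machinery and reproducibility of the published *simulated*
study conditions, not calibration to any real clinic population.

## Weight metrics

For each subject with total body weight TBW (kg), height HT (cm) and BMI
(kg·m⁻²):

* lean body weight (semi-mechanistic, male):
  LBW = 9270·TBW / (6680 + 216·BMI);
* ideal body weight (Lorentz, male): IBW = HT − 100 − (HT − 150)/4;
* adjusted body weight: ABW_f = IBW + f·(TBW − IBW) with f = 0.25 and
  0.40.

The ABW formula is applied with the excess weight measured above IBW for
both correction factors (the structure of the 40 % form and the standard
definition of adjusted body weight). Useful exact properties, all under
test: IBW depends on height only; ABW(0) = IBW and ABW(1) = TBW; for any
BMI above 2590/216 ≈ 12, LBW < TBW; when TBW ≥ IBW the ordering
IBW ≤ ABW25 ≤ ABW40 ≤ TBW holds. Metric values are never rounded; doses
in IU per kg of a metric are applied to the unrounded value.

## The pharmacokinetic model

A two-compartment IV bolus model of a conventional full-length FVIII
product, with lean body weight as the size covariate:

| parameter | typical value | covariate | BSV (%CV) |
|---|---|---|---|
| CL (dL/h) | 1.88 | (LBW/51.1)^0.610 | 37.0 |
| Q (dL/h) | 1.90 | — | — |
| V1 (dL) | 30.0 | (LBW/51.1)^0.950 | 11.2 |
| V2 (dL) | 6.37 | — | — |

Between-subject variability is implemented as lognormal random effects,
`cl = cl_typ · exp(η)`, η ~ N(0, ω²) with ω² = ln(1 + CV²) — the standard
popPK convention, which keeps parameters positive, reproduces the stated
%CV exactly and makes the typical value the population median (both
properties are verified by Monte-Carlo in the test suite at 10⁵ draws).
No η-correlation is imposed (none is reported for this model). Residual
unexplained variability (26.7 %CV proportional, 1.10 IU/dL additive) is
retained in `pk_model_spec()` as metadata but **not** applied: simulated
levels represent true activity, and the safety criterion is evaluated on
true levels. The PK covariate is always LBW, whatever metric the *dose*
is written against — dosing metric and PK covariate are independent axes.

The unit bolus response is the analytic bi-exponential
C(t) = A·e^(−αt) + B·e^(−βt) with α, β the roots of
λ² − (k10+k12+k21)λ + k10·k21 and A + B = 1/V1; multi-dose profiles are
exact superpositions of shifted copies plus an additive endogenous
baseline (0.5 IU/dL by default; 0 for the severe-mutation scenario; the
baseline never scales with dose). A numerically integrated ODE solution
(`deSolve`, stiff solver with bolus events) serves as an independent
oracle in the tests — agreement within 0.1 % relative across random
parameter draws — but is never the production path. If the two phase
rates coincide to machine precision, `macro_constants()` falls back to a
flagged one-compartment profile; with this model's constants that branch
is unreachable.

Units are fixed throughout: activity IU/dL, doses IU, volumes dL,
clearances dL/h, time h. 100 IU/dL is normal activity; the trough target
is 1 IU/dL.

## Regimen simulation and endpoints

Profiles are evaluated on a 0.2 h grid. Dosing runs from t = 0 for four
run-in weeks; the fifth week [672 h, 840 h) is analysed. Four weeks
suffice: the terminal half-life at typical parameters is ≈ 14 h, and the
week-4 vs week-5 weekly troughs agree within 1 % (tested). Because a week
is 3.5 dosing intervals of the q48h schedule, weekly windows are compared
as windows, not at fixed clock times.

Conventions, fixed and tested:

* **Troughs at dose instants.** A bolus is instantaneous; at a dose time
  the profile has both a pre-dose and a post-dose value. The analysis
  week uses the *pre-dose* value at dose instants, so grid points at
  troughs represent the trough. `concentration_profile(..., predose =)`
  exposes both conventions.
* **Safety**: a subject is safe if weekly C_min ≥ 1 IU/dL (boundary
  counts as safe); a regimen is safe if the safe fraction reaches the
  criterion (default 0.95). "Time below target" counts grid points
  strictly below 1 IU/dL, × 0.2 h.
* **Quantiles** (median, the 5th–95th percentile interval reported as the
  90 % CI, the 95th percentile of time-below) use the inclusive
  linear-interpolation convention (R type 7), fixed here because the
  source analysis does not state one.
* **Weekly consumption**: a 168 h window alternately contains 3 or 4
  q48h doses, so q48h consumption is reported as the long-run average
  3.5 × the per-dose amount; M-W-F is exactly 2 × base + 1 × Friday dose.

## Dose titration

The titration grid is 2 IU/kg steps on 10–100 IU/kg and 10 IU/kg steps on
100–210 IU/kg, refined to 0.1 IU/kg on 20–30 IU/kg where the optima of
interest fall; optima are reported at grid resolution. Because profiles
are linear in dose and the weekly minimum of a positively scaled profile
scales with it, each subject has a closed-form critical dose
(1 − baseline)/(metric × per-IU weekly trough), and the safe ratio at
any grid dose is exact — no per-dose resimulation. The grid scan and a
monotonicity-exploiting binary search are both implemented and must agree
(tested on random cohorts); brute-force re-evaluation from full profiles
confirms the fast path at and just below each optimum. For the
Monday-Wednesday-Friday schedule the Monday/Wednesday dose is fixed (the
q48h optimum in the full study protocol) and the Friday dose is
escalated; the per-subject critical Friday dose is again closed-form,
as the pointwise maximum over the week of the deficit-to-cover divided by
the Friday unit response. An unreachable criterion at the grid maximum
returns an explicit non-achievable result rather than an error — this
occurs genuinely for M-W-F dosing with a 0 IU/dL baseline.

Two safety criteria are first-class: the 95 % criterion used for q48h
titration and the narrative Friday escalation, and a 90 % criterion used
for the M-W-F summary tables; `study_config()` carries both
(`criterion_q48h = 0.95`, `criterion_mwf = 0.90`).

## Seeds and reproducibility

Every stochastic step (population, BSV draws) takes an explicit seed and
restores the caller's RNG state. `run_full_study()` derives population
and BSV sub-seeds deterministically from one master seed, so the whole
study report — and the CSVs written by `write_study_report()`, whose
manifest records seed, config hash and package version — is
bit-reproducible.

## Problem sizes used in the tests

Module tests use cohorts of 10–60 subjects, which exercise every code
path in seconds. The reproduction tests and `scripts/acceptance.R` use
the full study conditions — 1000 subjects per BMI group, averaged over
ten replicate studies — which the closed-form titration path makes cheap
(a few minutes on one core). The Monte-Carlo calibration checks use 10⁵
parameter draws and a 10⁵-subject population against independent
moment/CV oracles.

## Known limitations and sensitivity

* Conclusions inherit the source popPK model (one product, mostly
  older-than-10 patients, adult BMI range 15–38 kg·m⁻²); brand effects
  and pediatric PK are out of scope, as is Bayesian individual-PK
  tailoring.
* The NHANES height distribution is parameterised, not resampled from
  NHANES records. Optimal doses are insensitive to this choice (the
  required dose per kg scales weakly, ≈ TBW^−0.39, through the
  LBW–clearance power law), and reproduce the published per-metric values
  within ±0.5 IU/kg on seed averages. *Derived differences between
  consumption values* are another matter: the across-metric consumption
  spread within a group is a difference of five numbers of ~5000 IU each
  and is dominated by sub-IU/kg grid jitter and by the height
  distribution; the overweight/obese spread reproduces, the
  normal-group spread does not compress to the published value under the
  default heights, and the corresponding check in the test suite
  documents this as a known sensitivity.
* Bleed-risk modelling from time spent below target, and cost modelling
  beyond the $1/IU proportionality, are out of scope.
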