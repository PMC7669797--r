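---
title: "Estimating lifetime revision risk: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lifetime revision risk: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revrisk)
```

## The estimation problem

Implant survivorship studies observe a cohort of knee replacements for a
decade or two and record, for each knee, a follow-up time and whether the
implant was revised. Patients, however, want to know the probability of
*ever* needing a revision. That quantity depends on two competing
processes — the revision hazard of the implant and the mortality of the
patient — and on the age at surgery, because an 85-year-old has far less
remaining lifetime in which a revision can occur than a 55-year-old.
`revrisk` chains the standard tools for this problem: a parametric model
of the revision hazard fitted to the censored data, extrapolated through
a discrete-time multi-state cohort model in which death, taken from an
annual life table, competes with revision.

## The survival stage

Time to revision is modelled with six families, all in their usual
survival parameterizations:

| family        | parameters          | survival function |
|---------------|---------------------|-------------------|
| exponential   | `rate`              | `exp(-rate*t)` |
| Weibull       | `shape, scale`      | `exp(-(t/scale)^shape)` |
| Gompertz      | `rate, shape`       | hazard `rate*exp(shape*t)`, `shape` sign-free |
| log-normal    | `meanlog, sdlog`    | `1 - Phi((log t - meanlog)/sdlog)` |
| log-logistic  | `scale, shape`      | `1/(1 + (t/scale)^shape)` |
| gen. gamma    | `mu, sigma, Q`      | log-location form |

The families span increasing, decreasing and non-monotone long-term
hazards, which is the point: extrapolation beyond the observed follow-up
is model-dependent, and AIC comparison across the set shows how much the
answer moves. The generalised gamma uses the log-location (Prentice)
form, which nests the Weibull at `Q = 1` and the log-normal at `Q -> 0`
and avoids the overflow pathologies of the classical shape–scale–power
form; the nesting is exploited both for initialisation and as a test
invariant (the maximised log-likelihoods must satisfy
gengamma ≥ Weibull ≥ exponential).

Fitting maximises the right-censored log-likelihood. The exponential
rate is the closed form events/time; the other families are optimised
numerically (Nelder–Mead then BFGS polish, relative tolerance 1e-10) on
an unconstrained scale — positive parameters log-transformed, sign-free
ones untouched — starting from the exponential fit with shape parameters
at their nested-null values. If the optimiser ever ends below its
starting log-likelihood the initial values are returned with
`converged = FALSE`; in practice this guards against the generalised
gamma's flat ridges at low event counts. Deaths and withdrawals are
treated as non-informative right censoring here; mortality re-enters in
the next stage, which is what makes this a competing-risks analysis
rather than a naive one.

No covariates are modelled. With ~50 events a pooled constant hazard is
about what the data can support, age dependence of the *outcome* enters
through mortality, and the observed rate differences between sexes and
ages in cohorts of this design are small; age- or sex-stratified fits
can be obtained by subsetting the cohort before `fit_parametric()`.

## The Markov stage

Three states — unrevised, revised, dead — in annual cycles, matching the
annual resolution of national life tables. From the unrevised state the
revision cause-specific hazard over cycle `t` is
`h_r = -log(S(t+1)/S(t))`, the mortality hazard at attained age `a` is
`h_m = -log(1 - qx(a))`, and the cycle resolves the two by the
constant-within-cycle-hazard formula: total exit probability
`1 - exp(-(h_r + h_m))` apportioned `h_r : h_m`. This is order-invariant
— unlike "revision first, then death" sequencing — and exact when both
hazards are flat within the year, which at these magnitudes (`h_r` ~
0.006, `h_m` ≤ ~0.5) they effectively are. `qx` is capped at
`1 - 1e-12` before the log so the closing row of the table cannot
produce an infinite hazard. The revised state is absorbing except for
death at the general-population `qx`: re-revision is outside the model's
endpoint (first revision), and revision is assumed not to alter
mortality — the data to relax either assumption are rarely available.

The trace propagates expected occupancy deterministically from
(1, 0, 0); the published style of "simulating a cohort of 1000 patients"
is reproduced in expectation without Monte-Carlo noise, and
`run_microsim()` provides the individual-level stochastic counterpart
for illustrating variability. No half-cycle correction is applied to the
occupancies; instead person-time for the incidence-rate validation uses
trapezoid occupancy (mean of cycle-start and cycle-end), which keeps the
no-mortality oracle — predicted incidence equals the generating hazard —
accurate to well under 1%. Lifetime revision risk is the sum of newly
revised mass over all cycles; under flat hazards it collapses to the
closed form `h_r / (h_r + h_m)`, which the tests check exactly. The
model stops at age 110, where the fixture table closes; residual
unrevised mass there (numerically zero) contributes no revision.

Scenarios rescale `h_r` multiplicatively, either globally (to impose,
say, a registry-level revision rate, which the user must supply) or at
attained ages above a threshold — the halve-above-90 scenario encodes
the clinical reality that very elderly patients are seldom offered
revision. Lifetime risk is monotone in these multipliers, a property the
tests exercise.

## The synthetic cohort and life-table fixtures

The generator emulates a single-centre consecutive series: 1000 knees
from ~820 patients (22% of patients bilateral; both knees share the
patient's age, sex, entry and death time but revise independently), age
truncated-normal 66.6 ± 9.6 on [33, 88] (rejection sampling — exact and
cheap at <1% rejected mass), 49% female, entry uniform over a
10.75-year recruitment window with study close 5 years after the last
entry, so potential follow-up is uniform on [5, 15.75] with mean ~10.4
years. Revision times are exponential at 0.0057/year — calibrated so a
default cohort produces on the order of 50 revisions over its ~8,500
at-risk implant-years — death times follow the life table at the
attained age (year-by-year walk, uniform within the year of death), and
4.2% of knees withdraw at a uniform time. Observed follow-up is the
minimum of the four processes.

Mortality comes from a Gompertz–Makeham fixture,
`hazard = A + B*exp(C*age)` with A = 2e-4, B = 2.5e-5, C = 0.095,
sex-pooled, integrated exactly over each year of age to give `qx`. Its
remaining life expectancies (27.4 / 19.2 / 12.3 / 7.0 years at ages
55/65/75/85) sit where recent national tables for an older surgical
population do. Real analyses should substitute the applicable national
table via `read_life_table()`; the two open calibration questions a real
table would settle — which edition, and how male and female tables are
weighted for a 49%-female cohort — are exactly what the sex-pooled
fixture glosses over.

What the generator deliberately does *not* emulate: correlation between
a patient's two knees beyond shared mortality, age- or sex-dependent
revision hazards, non-constant (e.g. early-failure) hazard shapes, BMI
and diagnosis effects, and informative withdrawal. Tests passing on
these cohorts therefore demonstrate that the estimation machinery is
correct under its stated assumptions — unbiased hazard recovery,
calibrated intervals, exact oracles — not that the constant-hazard model
is adequate for any particular real registry; that judgement is what the
AIC comparison and incidence validation are for on real data.

One consequence of fixture mortality worth knowing: the fixture kills
more person-time than a real surgical cohort (surgical patients are
selected for fitness), so observed mean follow-up (~8.6 years) sits
below potential mean follow-up (~10.4 years). Summaries report both.

## Uncertainty

Percentile bootstrap, 250 replicates by default: resample the cohort
with replacement (knees by default; patients as the clustered
alternative), refit the family, rerun the Markov model, take the 2.5th
and 97.5th percentiles of the replicate risks. Percentile rather than
BCa because the estimand is a smooth near-linear functional of a
one-parameter fit in the base case, where percentile intervals are
already close to nominal — the coverage test confirms ~95% — and
because it is the simplest method consistent with reporting quantile
intervals. Zero-event resamples (possible in small cohorts) are redrawn
with a cap of ten times the replicate budget, since a zero-event
parametric fit is undefined; redraws are counted and reported.

## Problem sizes and numerical tolerances in the tests

The suite runs the full pipeline at the study scale (cohorts of 1000;
200 replicate cohorts for calibration; 250 bootstrap replicates for the
headline interval) and scales supporting simulations to what their
Monte-Carlo error requires: parameter recovery at n = 2000 × 8
replicates per family, coverage at 40 cohorts × 60 replicates,
microsimulation agreement at n = 20,000. Exact identities (closed-form
MLE, occupancy conservation at 1e-12, flat-hazard lifetime risk at
1e-8, likelihood nesting at 1e-6) are tested at tight tolerances;
stochastic reproductions use 3-standard-error or published-interval
bands. Maximised likelihoods are cross-checked against an independent
implementation (`flexsurv`) to 1e-4.

## Known limitations

- The constant-hazard base case underestimates risk if late wear-out
  accelerates revision beyond the observed window; the Gompertz and
  generalised-gamma fits bound that sensitivity but inherit the same
  short-follow-up information limit.
- Lifetime risk at young entry ages leans heavily on extrapolated
  decades; intervals reflect sampling noise in the fit, not structural
  model uncertainty between families.
- General-population mortality overstates the death hazard of surgical
  patients in the first years (healthy-cohort effect), which slightly
  *lowers* estimated lifetime revision risk.
- The bootstrap resamples the revision data only; life-table uncertainty
  is ignored, as is any frailty shared between a patient's two knees
  beyond their common death time.
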