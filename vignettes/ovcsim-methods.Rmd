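---
title: "Modeling chemotherapy implementation strategies in stage IIIC ovarian cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling chemotherapy implementation strategies in stage IIIC ovarian cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovcsim)
```

## The model

`ovcsim` is a decision-analytic model of post-operative chemotherapy for
women newly diagnosed with stage IIIC epithelial ovarian cancer. Patients
enter at age 63 and are triaged to primary cytoreductive surgery (PCS,
74.5%) or neoadjuvant chemotherapy followed by interval cytoreductive
surgery (NACT+ICS, 25.5%). Along the PCS branch, patients face a 4.0%
90-day surgical mortality, continue to adjuvant chemotherapy with
probability 90.7% (non-continuers receive *partial* treatment), and are
completely/optimally cytoreduced with probability 89% (11% suboptimal).
Along the NACT branch, patients continue to ICS with probability 82.1%
(non-continuers receive partial treatment without surgery), face a 2.3%
90-day surgical mortality, and split into complete/optimal versus
suboptimal cytoreduction.

A chemotherapy **strategy** assigns, to each (arm, cytoreduction) cell, a
probability distribution over five regimens: standard IV chemotherapy
(reference), IP+IV (hazard ratio 0.75 for overall survival vs standard),
bevacizumab+IV (HR 0.85), HIPEC+IV (HR 0.67) and dose-dense IV (HR 1 in
the base case; 0.79 in the dose-dense scenario). Five strategies are
compared: current practice (IP+IV 41% of eligible PCS patients,
bevacizumab 4% of suboptimal PCS patients, no HIPEC), full optimized
implementation (100% of each eligible cell), and three single-component
strategies optimizing one regimen at a time.

Survival is modeled on a one-month cycle over a lifetime horizon. Every
treated or partial pathway transforms one **baseline curve** — overall
survival of the reference pathway (NACT+ICS, complete/optimal
cytoreduction, standard IV) — by proportional hazards on the discrete
grid, \(S_{\mathrm{adj}}(t) = S(t)^{h}\), where \(h\) is the product of a
pathway-level multiplier and the regimen hazard ratio. Patients surviving
12 years from diagnosis are considered cured and thereafter face only
age-specific all-cause mortality from a lifetable; survival is forced to
zero when the attained age reaches 110. Surgical deaths are spread
uniformly over months 1–3.

Mean life expectancy (LE) is the half-cycle-corrected area under the
monthly curve, \(\sum_t (S(t-1)+S(t))/2\); the median is reported as
\(m - 0.5\) where \(m\) is the first month with \(S(m) < 0.5\). Both
conventions follow from the one-month cycle; all published medians for
this model end in .5, consistent with the half-month grid.

### Assumptions worth stating

* **Proportional hazards as survival powering.** \(S^h\) is exact under
  proportional hazards and guarantees valid curves for any \(h > 0\);
  scaling per-cycle death probabilities instead would only approximate it.
* **Background mortality before cure is not added.** The baseline curve
  derives from registry overall survival, which already embodies other-
  cause deaths; adding lifetable mortality before the cure month would
  double count it.
* **Branch independence.** Triage, surgical death, continuation and
  cytoreduction are treated as independent multiplicative branches;
  continuation probabilities are read as conditional on surviving surgery,
  and cytoreduction status is assigned only to patients who reach the
  relevant treatment decision.
* **Partial treatment** carries a single calibrated hazard multiplier
  shared by both arms rather than its own fitted curve.

## Calibration of unpublished inputs

The published analysis reports model *outputs* (LE and median survival per
strategy) but not the underlying reference curve or the pathway-level
hazard multipliers. `calibrate()` recovers them by least squares against
the ten printed primary statistics, using the deterministic cohort solver
inside the objective:

* baseline curve: Weibull with scale and shape free. The implemented
  family is a mixture-cure Weibull
  \(S(t)=\pi+(1-\pi)e^{-(t/\sigma)^k}\), but the default calibration fixes
  the plateau \(\pi = 0\). The structural cure at 12 years already carries
  long-term survivorship, so a free plateau is nearly unidentified by the
  primary statistics (the fitted-parameter Jacobian exposes this), and its
  value is pinned down only by behaviour beyond the cure month — exactly
  where it degrades extrapolation when the cure time is varied in
  sensitivity analysis. Freeing it is available via `fix = NULL`.
* pathway multipliers for PCS complete/optimal, PCS suboptimal, NACT
  suboptimal and partial treatment (the NACT complete/optimal reference is
  fixed at 1), and the NACT cytoreduction split.

LE targets carry weight 1, median targets weight 0.5. Because the
reported median is quantized to the half-month grid, the objective scores
medians through the continuous 0.5-crossing of the mixture curve with a
±0.45-month dead band around the printed value: any crossing inside the
target month reproduces the printed median exactly, so only crossings
within 0.05 months of a month edge are penalized. (Penalizing distance
from the month center instead couples the median terms to the LE terms
and leaves LE residuals two orders of magnitude larger.) Optimization is
Nelder–Mead in a logit-transformed box, run from a fixed grid of ten
starts with early stopping once every residual is within a quarter of the
0.2-month acceptance tolerance, followed by a Levenberg–Marquardt
refinement of the residual vector, which is smooth wherever the median
crossings sit inside their dead bands; with seven free parameters against
five LE equalities and five median interval constraints the refinement
typically drives all residuals to numerical zero. The whole procedure is
deterministic. The fit is *accepted* only if every residual — grid
medians included — is at most 0.2 months; otherwise `calibrate()` reports
failure rather than silently returning the best attempt.

Calibrated values are stand-ins constrained by printed outputs, not
estimates of the original registry fits; the evidence they suffice is
held-out agreement: `validate_heldout()` recomputes the published
sensitivity analyses that the calibration never saw (imperfect
implementation at 60–90%, hazard-ratio confidence bounds, the
bevacizumab-null scenario, cure at 8/16 years, IP uptake at 50/150%, and
the dose-dense scenario) and tabulates deviations; all lie within ±1
month of print, most within ±0.25.

## Solver and microsimulator

`solve_strategy()` is the expectation engine: it mixes pathway curves by
probability, \(S_{\mathrm{mix}}(t)=\sum_i p_i S_i(t)\), and reads LE and
median off the mixture. LE linearity over pathways is checked internally
to 1e-9 every call. All experiment drivers use the solver, so scenario
tables are deterministic and identical across reruns.

`simulate_cohort()` is the individual-level Monte Carlo counterpart: each
patient samples a pathway from the enumerated probabilities and a death
month by inverse transform from that pathway's curve, with a single seeded
RNG stream. It exists to validate the solver (agreement within 3 standard
errors at n = 200,000 per strategy is part of the test suite) and to
produce patient-level output; it plays no role in the reported scenario
tables, which keeps Monte Carlo noise out of them. Cohort sizes in the
tests (10^3–2×10^5) were chosen so the whole suite solves in minutes while
keeping the standard error of LE near 0.1 months at the largest size.

## Scenario semantics

* **Imperfect implementation** multiplies every non-standard regimen
  probability in a cell by the implementation fraction *f*, with the
  remainder reverting to standard IV.
* **Dose-dense, current practice**: 15.2% of *all* PCS patients receive
  dose-dense instead of standard IV. Only patients reaching chemotherapy
  can receive it, so the share is rescaled by survival and continuation
  and drawn proportionally from the standard-IV mass of both cytoreduction
  cells; IP and bevacizumab mass is untouched. **Dose-dense, optimized**:
  suboptimally cytoreduced PCS patients receive dose-dense in place of
  bevacizumab.
* **IP-uptake sensitivity** evaluates 50% and 150% of the base uptake
  (0.205 and 0.615 exactly; published rounding is 0.21/0.62).
* **Cure-time sensitivity** moves only the cure month; the calibrated
  baseline stays fixed, so results beyond 12 years are extrapolation of
  the Weibull — the main reason the plateau is fixed at zero (above).

## Synthetic data

The study's external inputs are emulated so the pipeline runs end to end
without restricted data:

* `make_lifetable()` builds a female all-cause lifetable from a
  Gompertz–Makeham hazard. Defaults (Makeham 5e-4, level 1.2e-5, slope
  0.103/yr) give a remaining life expectancy of 21.4 years at age 63 and
  annual death probabilities of 0.008 at 63 and 0.074 at 85 — plausible
  for a contemporary US female table, but a documented emulation, not a
  fit.
* `make_registry_extract()` draws patient-level records (diagnosis age,
  arm, cytoreduction, follow-up, death indicator) for the reference
  pathway from a chosen baseline, with uniform administrative censoring.
  Its Kaplan–Meier estimate converges to the generating curve, and
  refitting the mixture-cure family to a large extract recovers that curve
  to sup-norm < 0.01 — evidence the calibration family can represent
  registry-style data.

What synthetic data do **not** establish: agreement with the actual
registry case mix (age heterogeneity, comorbidity, center effects are
absent), non-proportional hazards of real regimens, or the coding quirks
of registry extracts. Passing tests show internal consistency of the
model and faithfulness to the published outputs, not external validity.

## Numerical choices and degenerate inputs

* Curves are validated on construction (start at 1, non-increasing,
  within [0, 1]) and clamped against floating-point drift.
* Hazard ratios must be strictly positive; annual death probabilities are
  converted to monthly via \(1-(1-q)^{1/12}\).
* A curve whose terminal survival exceeds 0.001 triggers a truncation
  warning in `life_expectancy()`; a curve never crossing 0.5 makes
  `median_survival()` error rather than return a fabricated value.
* Calibration with a single free parameter switches from Nelder–Mead to
  Brent's method (reliable 1-D bounded search).
* An all-zero lifetable, degenerate triage probabilities (e.g. everyone
  dying surgically) and cure times beyond the horizon are all legal inputs
  with defined behaviour, exercised in the tests.

## Known limitations

The model reproduces a published population-level analysis: it has no
recurrence or progression states, no treatment toxicity or quality-of-life
adjustment, no patient-level covariates, and no costs. Calibrated pathway
multipliers are identified only up to the printed outputs; they should not
be interpreted as clinical effect estimates. Medians inherit the
half-month grid, so median differences are only resolved to whole months.
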