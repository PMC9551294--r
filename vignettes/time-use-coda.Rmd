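---
title: "Compositional analysis of accelerometer time use: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of accelerometer time use: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timeusecoda)
```

## The problem

Waking time is finite: minutes spent in moderate-to-vigorous physical
activity (MVPA) are necessarily minutes not spent sedentary (SB) or in
light activity (LPA). Regressing a health outcome on absolute minutes of
one behaviour while "adjusting" for the others is therefore ill-posed —
the three durations are linearly constrained, and conventional models can
overstate or understate effects. Compositional data analysis (CoDa)
resolves this by treating the day as a *composition*: only the relative
shares of wear time carry information, and inference is done in a log-ratio
geometry where the constraint disappears.

This package implements that full chain for epoch-level accelerometry and
a continuous brain outcome (hippocampal volume in community-dwelling older
adults, the setting its defaults are calibrated to): device-level
screening, composition construction, pivot isometric log-ratio (ilr)
regression over nested covariate models, and time-reallocation prediction.
A seeded synthetic-cohort generator with known ground truth makes every
stage testable without participant data.

## Accelerometer screening

Epochs are 60 s with an estimated MET value; a MET of 0 encodes absence of
an acceleration signal. The screening rules, all overridable in
`pipeline_config()`:

* **Non-wear**: any run of consecutive zero-MET epochs *strictly longer*
  than 60 minutes (`detect_nonwear()`). The wording "longer than 60
  minutes" is implemented strictly (`> 60`); because conventions vary
  across the accelerometry literature, `strict = FALSE` gives the
  inclusive rule. No interruption allowance is applied inside a run.
* **Intensity bands** (`classify_intensity()`): SB at MET ≤ 1.5, MVPA at
  MET ≥ 3.0, LPA between. The operative cut-points are the continuous
  thresholds 1.5 and 3.0; a displayed band of "1.6–2.9" reflects the 0.1
  MET display resolution of consumer devices, so values in (1.5, 1.6) are
  light activity.
* **Valid day**: ≥ 600 wear minutes (10 h). **Valid participant**: ≥ 4
  valid days. Totals and means are computed over valid days only.

Every day satisfies `sb + lpa + mvpa = wear` by construction, and zero-MET
epochs never contribute to wear whether or not they sit in a flagged
non-wear run (a short signal gap is still not wear).

Participant compositions divide each behaviour's *pooled* total minutes
over valid days by the pooled wear time (`participant_composition()`),
so longer-wear days weigh more. Whether pooling or averaging daily
proportions is the better estimator is genuinely open; the day-mean
variant (`method = "daymean"`) is provided for sensitivity analysis, and
in practice the two differ little when wear time is stable.

## Compositional geometry

With closed shares $(t_{SB}, t_{LPA}, t_{MVPA})$, the MVPA-first pivot
coordinates are

$$z_1 = \sqrt{\tfrac{2}{3}}\,
  \ln\frac{t_{MVPA}}{\sqrt{t_{SB}\,t_{LPA}}},\qquad
  z_2 = \sqrt{\tfrac{1}{2}}\,\ln\frac{t_{LPA}}{t_{SB}},$$

an orthonormal log-ratio basis: $z_1$ carries the focal behaviour's share
relative to the geometric mean of the rest, $z_2$ the contrast of the
remaining two. Refitting with each behaviour pivot-first yields one
interpretable $z_1$ coefficient per behaviour; the three refits are the
same model in rotated bases, so fitted values are identical and the three
$z_1$ coefficients sum to zero exactly — both facts are verified at fit
time and in the test suite. The generic completion fixes
$z_2 = \sqrt{1/2}\,\ln(\text{third}/\text{second})$; any other orthonormal
completion changes nothing observable except the sign of $z_2$, so only
the $z_1$ reporting convention matters.

Supporting operations: `close_composition()` (closure),
`variation_matrix()` (variances of pairwise log-ratios, $n-1$ divisor —
the standard sample variance; small entries mean near-proportional
behaviours), `compositional_mean()` (closed geometric means), and
`replace_zeros()` (multiplicative replacement). Zeros are rare at the
participant level — a zero requires no MVPA epoch across ≥ 4 valid days —
but structural zeros would otherwise break every log-ratio; the default
detection limit is 0.65 × the smallest observed non-zero share of that
part, shrinking the other parts proportionally, with `"fail"` available
when silent imputation is unacceptable. Replacement counts are logged by
the pipeline.

## Regression models

`fit_pivot_models()` regresses the outcome on $(z_1, z_2)$ plus nested
covariate sets: model 1 unadjusted; model 2 + sex, age, intracranial
volume (ICV); model 3 + education (≥ 13 y); model 4 + BMI category
(< 18.5 and ≥ 25.0 indicators against 18.5–24.9), smoking, heavy alcohol
use (≥ 60 g ethanol/day); model 5 + medication for hypertension,
dyslipidemia and diabetes. Fitting is ordinary least squares with
classical $t$ inference on $n - p$ degrees of freedom; no robust errors
are used, matching standard practice for this design, and missing
covariates are handled by listwise deletion with a logged count. Rank
deficiency (e.g. a constant covariate in a small stratum) is a hard,
named error rather than a silent drop. As a sensitivity analysis the
suite also fits volume/ICV as the outcome ("proportion of hippocampal
volume"), excluding ICV as a covariate; those coefficients are reported
in $10^{-6}$ units.

## Reallocation prediction

A fitted compositional effect is stored basis-free as a log-contrast
vector $a$ with $\sum_i a_i = 0$ (`log_contrast()`,
`log_contrast_from_pivot()`); the conversion from the three pivot-first
coefficients is $a_i = \sqrt{2/3}\,(b_i - \bar b)$, with centring
absorbing rounding when the $b_i$ come from a published table.
`reallocate()` shifts the focal share by $\delta$ percentage points of
wear time, the balance absorbed equally by the other two behaviours
(default, the convention used for published reallocation figures) or
proportionally to their base shares (equivalently, holding $z_2$
constant). The predicted outcome difference is

$$\Delta\hat y = \sum_i a_i\,(\ln x_i^{new} - \ln x_i^{base}),$$

computed in parallel through the ilr-coordinate path and cross-checked at
$10^{-10}$ on every call. Because the focal share enters through its
logarithm, predictions are asymmetric: removing time from a small
behaviour like MVPA costs more than adding the same time gains.

Two base-composition conventions exist. The *arithmetic* base (closure of
the mean daily minutes) is the default because it is the convention under
which published reallocation magnitudes for this design reproduce; the
*compositional* (geometric) mean — the centre usually quoted in figure
captions, with a visibly smaller MVPA share (≈ 4.6% vs ≈ 6.0% here) — is
available via `realloc_base = "geometric"`. The choice is surfaced in the
run log. Minutes equivalents use the cohort mean wear time unless
overridden. Point predictions only; no interval is attached, since the
delta-method band would suggest precision the base-composition ambiguity
does not support.

## The synthetic cohort

`cohort_config()` defines the generator; its defaults *are* the study
conditions the pipeline is calibrated to and are not tuned per analysis:

* 485 participants × 7 days; 47% male; age ~ N(73.3, 5.5²) truncated to
  65–84; ICV ~ N(1,432,369, 152,092²) mm³; education 19.6%, BMI < 18.5
  8.2%, ≥ 25 17.7%, smoking 8.5%, heavy alcohol 4.5%, medication 45.6 /
  34.4 / 9.5%.
* Compositions are logistic-normal: pivot coordinates drawn from a
  bivariate normal and inverted through `ilr_inverse()`. The location is
  the pivot image of the 50.5 / 44.9 / 4.6% centre; the covariance is
  *derived* from the target pairwise log-ratio variances (0.26, 1.19,
  0.76) via the clr relation $\Sigma = -\tfrac12 G T G$ rotated into the
  pivot basis — so the generator reproduces the published variation
  matrix, including MVPA/SB as the most variable ratio, by construction
  rather than by tuning. No population model for time-use compositions is
  canonical; the logistic-normal is the natural choice on the ilr scale
  and guarantees positivity.
* Outcomes follow the model-5 structure:
  intercept + $\beta_{z1} z_1 + \beta_{z2} z_2$ + covariate effects +
  N(0, σ²), with true $\beta_{z1}$ 57.1 (right) / 17.5 (left) mm³ per ilr
  unit and $\beta_{z2}$ the orthogonal contrasts implied by the same
  fitted models (−6.7 / −50.4). The intercept is solved so the expected
  outcome hits the target means (3687.7 / 3522.1 mm³); σ is solved so the
  marginal SD hits 420.3 / 391.1 mm³ after the linear predictor's
  variance is accounted for (σ ≈ 331 / 296 mm³). Covariate effect sizes
  are plausible for this literature (e.g. −20 mm³ per year of age,
  0.0015 mm³ per mm³ ICV) but are conventions, not estimates; covariates
  are independent of the composition unless the `age_confounding` knob is
  set, which shifts $z_1$ with standardised age for stress tests.
* Wear time has a person level: habitual wear ~ N(887.5, 109.4²) min/day
  between participants, daily wear ~ N(habitual, 60²) within, clipped to
  600–1380 so simulated days are valid; daily minutes apportion the true
  composition by largest remainder, and `simulate_day_epochs()` lays them
  out as bouted MET values (bouts ≤ 45/30/15 min for SB/LPA/MVPA, MET
  uniform within band at 0.1 resolution) with the non-wear remainder as
  leading/trailing zero runs. Screening a generated stream recovers the
  intended minutes *exactly*, which is what makes the epoch layer
  testable end to end.

What the generator does **not** emulate: the joint distribution of
covariates and activity (only marginals are published for the target
population), day-of-week and seasonal structure, within-day circadian
patterning beyond bouts, device MET-estimation error, missing covariates,
and MRI segmentation error. Green tests therefore demonstrate that the
*pipeline* is correct under a faithful marginal emulation — not that the
scientific findings would replicate in new data.

Determinism: covariates/compositions, outcomes, and epochs use seeds
`seed`, `seed + 1`, `seed + 2`, so the whole bundle is byte-reproducible
given one integer.

## Numerical choices and test resolution

Closure and round trips are exact to 1e-12; pivot invariance of fitted
values to 1e-8 (OLS through two QR factorisations); the zero-sum of pivot
coefficients to 1e-8. Largest-remainder apportionment breaks ties by
column order, deterministically. Degenerate inputs fail loudly: all-zero
compositions, zero-MET epochs passed to the classifier, infeasible
reallocations (with the feasible range in the message), rank-deficient
designs (with the offending columns named).

Monte Carlo resolution matters when judging estimator recovery: with the
default calibration the per-replicate standard error of the MVPA $z_1$
coefficient at n = 485 is ≈ 21 mm³, so a 200-replicate mean resolves the
true 57.1 only to about ±1.5 mm³ (1 SE) — roughly the size of a 2%
band — and individual replicate batches can land 2–3 SE out. Extended
runs (1000 replicates, several seed schemes) center on the truth, and a
noiseless cohort recovers it exactly; recovery checks at the
200-replicate scale should be read with that resolution in mind. Problem
sizes used in the shipped tests (cohorts of 6–485, 10⁴ round-trip
compositions, 10³ random days against the brute-force non-wear scan) were
chosen to keep the default suite fast while exercising every rule
boundary.

## Known limitations

Only 3-part compositions are supported (the design needs no more);
balances other than pivot coordinates, robust/Bayesian zero imputation,
bout-level MVPA metrics, sleep segmentation, and interval estimates for
reallocation predictions are out of scope. The cross-sectional regression
carries no causal interpretation; reallocation predictions are model
extrapolations along a one-dimensional path in the simplex.
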