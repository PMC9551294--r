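# timeusecoda

Compositional data analysis of accelerometer-measured time use and
hippocampal volume, as a tested end-to-end R pipeline.

Daily waking time splits into sedentary behaviour (SB), light physical
activity (LPA) and moderate-to-vigorous physical activity (MVPA). Because
the three durations compete for the same finite wear time, they are
analysed here as a **composition**: only relative shares carry
information, and regression is done in isometric log-ratio (ilr)
coordinates. The package covers the whole chain used in accelerometer +
MRI studies of older adults, and ships a calibrated synthetic-cohort
generator with known ground truth so every stage is testable without
participant data:

1. **Accelerometry screening** — 60-s MET epochs; non-wear = zero-signal
   runs longer than 60 min; valid day ≥ 10 h wear; valid participant ≥ 4
   valid days; bands SB ≤ 1.5 MET, LPA in between, MVPA ≥ 3.0 MET.
2. **Compositional geometry** — closure, multiplicative zero replacement,
   the variation matrix, compositional mean, and pivot ilr coordinates

   z1 = √(2/3) · ln( t_MVPA / √(t_SB · t_LPA) ),  z2 = √(1/2) · ln( t_LPA / t_SB )

   with each behaviour refitted pivot-first for one interpretable
   coefficient per behaviour.
3. **Regression** — OLS of hippocampal volume on (z1, z2) across five
   nested covariate models (unadjusted → sex/age/ICV → + education →
   + BMI/smoking/alcohol → + medications), plus volume/ICV sensitivity
   outcomes.
4. **Reallocation** — predicted outcome difference when a fixed share of
   wear time moves into or out of one behaviour, via the basis-free
   log-contrast form of the fitted model.

## Worked example

Predict the volume difference for a 3 percentage-point MVPA reallocation
using published fully-adjusted pivot coefficients (SB −22.7, LPA −34.3,
MVPA 57.1 mm³/ilr) at the cohort-mean composition:

```r
library(timeusecoda)
lc   <- log_contrast(c(sb = -22.7, lpa = -34.3, mvpa = 57.1))
base <- close_composition(c(sb = 442.7, lpa = 391.2, mvpa = 53.6))
predict_difference(lc, base, "mvpa", -3, wear_min = 887.5)
#>    focal delta_pp minutes_equiv    new_sb   new_lpa   new_mvpa predicted_diff
#> sb  mvpa       -3        26.625 0.5138169 0.4557887 0.03039437      -33.48178
```

Moving 3 pp of wear time (26.6 min/day at 887.5 min wear) out of MVPA
predicts a 33.5 mm³ smaller right hippocampal volume; the reverse shift
predicts only +20.3 mm³ — the asymmetry is the log-scale curvature around
a small MVPA share.

Fitting the suite on a synthetic cohort (all computation lives in the
package; the numbered scripts under `analysis/` run the same stages at
full scale):

```r
cfg <- pipeline_config(cohort = cohort_config(n_participants = 485, seed = 2017))
res <- run_pipeline(cfg, "results/run")
fit_pivot_models(res$analysis, 5, "right_hipp_mm3")
#> Compositional regression: right_hipp_mm3, model 5 (n = 485)
#>   SB   z1 beta    -33.5  (-105.7 to 38.7)  p = 0.362
#>   LPA  z1 beta    -26.5  (-117.6 to 64.6)  p = 0.568
#>   MVPA z1 beta     60.0  (15.1 to 104.8)  p = 0.009
```

The true MVPA effect in this generator is 57.1 mm³/ilr; the three betas
sum to zero exactly, and the three pivot refits share identical fitted
values. `results/run/` contains the descriptives table, variation matrix,
coefficient tables, reallocation curve and a JSON run log with the full
exclusion cascade.

## The analysis workflow

`analysis/01_simulate.R` … `05_reallocate.R` are thin narrative drivers
over the package: simulate the cohort, screen epochs (verifying that
screened minutes match the generator's intent exactly), write
descriptives and the variation matrix, fit the model suite, and produce
the reallocation curve and figure. Outputs land under `results/`.

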