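# pubgrowth

Growth curve analysis of the pubertal spurt with the SITAR
(SuperImposition by Translation And Rotation) shape-invariant
nonlinear mixed-effects model, for auxologists and epidemiologists
working with longitudinal anthropometry (height, sitting height, limb
lengths and widths) in cohorts followed across puberty.

## The model

All subjects share one natural cubic spline mean curve `h`; each
subject's curve is that mean curve shifted and stretched by three
normally distributed random effects:

    y_ij = alpha_i + h[(x_ij - beta_i) * exp(gamma_i)] + e_ij,
    e_ij ~ N(0, sigma_r^2)

* **size** `alpha_i` (cm) — an up/down shift: how tall the subject is;
* **timing** `beta_i` — a left/right shift: age at peak velocity (APV),
  positive for late developers;
* **intensity** `gamma_i` — an age-scale compression: peak velocity
  (PV), positive for fast developers.

Age is modelled on the log scale by default (timing differences are
then proportional, and the timing SD × median age gives years). On top
of the fit the package provides velocity and percent-velocity curves
with takeoff/peak landmark extraction, BIC selection of the spline
degrees of freedom, subject-level bootstrap SEs, iterative outlier
cleaning at |standardized residual| > 4, stratification of a cohort
into timing and intensity groups with local model refits,
cross-measurement random-effect correlation matrices with seriation,
and a synthetic-cohort generator with known ground truth for
validation.

## Worked example

Simulate a clinic-style cohort at the reference male-height parameters
(size SD 6.46 cm, timing SD 0.86 yr, intensity SD 0.13, residual SD
0.51 cm), fit, and read off the summary:

```r
library(pubgrowth)

truth <- harpenden_male_height_params()
sim <- simulate_cohort(truth, harpenden_design(n = 371), seed = 1)
fit <- fit_sitar(sim$data, df = 7)
fit
#> SITAR fit: 371 subjects, 4188 records, df = 7 (log age)
#>   random effects: size, timing, intensity
#>   RE SDs: size 6.4 cm, timing 0.0632 log-age ( 0.87 yr ), intensity 0.134
#>   residual SD: 0.501  logLik: -5509.5153  BIC: 11160.81

variance_explained(fit)   # % of cross-sectional variance explained
#> [1] 99.48586

find_landmarks(velocity_curve(fit))
#> peak:    9.43 cm/yr at 14.16 yr
#> takeoff: 4.66 cm/yr at 10.45 yr
```

The fitted SDs recover the generative truth (6.46 / 0.86 / 0.13 /
0.51), the model explains ~99.5% of variance as expected at this noise
level, and the mean curve peaks at 14.16 yr with PV 9.43 cm/yr against
a generative APV of 14.2 yr and PV of 9.3 cm/yr. Stratify the cohort
and compare local and globally predicted curves:

```r
pipe <- grouping_pipeline(sim$data, k_timing = 9, k_intensity = 5,
                          df_global = 6, df_local = 5)
group_summary(pipe$local_fits)
```

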