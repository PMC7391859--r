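Package: pubgrowth
Title: Shape-Invariant Growth Curve Modelling of the Pubertal Spurt
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the SITAR (SuperImposition by Translation And Rotation)
    shape-invariant nonlinear mixed-effects growth model: a common natural
    cubic spline mean curve plus per-subject size, timing and intensity
    random effects, fitted on a (log-) age axis. Provides distance,
    velocity and percent-velocity curves with takeoff and peak-velocity
    landmark extraction, BIC-based spline degrees-of-freedom selection,
    subject-level bootstrap standard errors, iterative standardized-residual
    outlier cleaning, global-to-local stratification of subjects by their
    timing and intensity random effects, cross-measurement random-effect
    correlation matrices with seriation, and a longitudinal cohort
    simulator with configurable visit designs for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    nlme,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
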