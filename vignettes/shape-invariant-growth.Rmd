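---
title: "Modelling the pubertal growth spurt with a shape-invariant spline model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the pubertal growth spurt with a shape-invariant spline model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Longitudinal anthropometry in puberty looks chaotic across individuals
because the adolescent spurt varies in three simple ways: how large the
child is, when the spurt happens, and how fast it is. The SITAR
(SuperImposition by Translation And Rotation) model formalises exactly
this. All subjects share one smooth mean curve; each subject's own curve
is that mean curve shifted and stretched:

$$y_{ij} = \alpha_i + h\big[(x_{ij} - \beta_i)\,e^{\gamma_i}\big] + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, \sigma_r^2)$$

where $y_{ij}$ is the measurement (cm) of subject $i$ at age $t_{ij}$,
$x$ is the working age axis, $h$ is a natural cubic spline, and the
subject random effects $(\alpha_i, \beta_i, \gamma_i)$ — *size*, *timing*
and *intensity* — are trivariate normal. Size is a vertical shift in cm;
timing is a horizontal shift, positive for late developers; intensity
stretches or compresses the age scale, so $e^{\gamma}$ acts as a
multiplier on growth rate. Because timing corresponds directly to the age
at peak velocity (APV) and intensity to peak velocity (PV), the model's
random effects quantify the classical "tempo of growth".

By default age enters after natural log transformation
($x = \log t$), which measures age differences proportionally rather
than in years and generally improves the fit in puberty. Results are
reported back on the year scale: the timing SD is multiplied by the
median observation age to give years, and velocity uses the chain rule
$dy/dt = (dy/dx)/t$.

### The pivot of the age scaling

The intensity factor $e^{\gamma}$ rescales the (log-) age axis around a
pivot. We centre the axis at the log of the median observation age, so
scaling pivots at the centre of the data. This choice matters in
practice: pivoting at $x = 0$ (i.e. age 1 yr on the log scale) makes an
intensity change almost indistinguishable from a timing shift — in
experiments the two parameters' estimated correlation approached 1 and
the optimisation diverged — whereas the centred pivot separates them
cleanly. It is also the convention the "timing SD × median age"
conversion presupposes. The synthetic-cohort generator uses the same
pivot, so generative and fitted parameters mean the same thing.

### Fixed effects and identifiability

The spline coefficients (plus an explicit intercept) define the mean
curve; timing and intensity each get a fixed effect ($\beta_0,
\gamma_0$) so the corresponding random effects have mean zero. There is
no separate size fixed effect — the spline intercept plays that role.
When a model omits a random effect (the grouped local models below
condition on timing and/or intensity), the matching fixed effect is
omitted too: its only purpose is to centre the random effect, and
without the random effect the timing gradient lies so close to the
span of the spline basis that keeping it makes the fit singular.

## Estimation

Models are estimated by maximum likelihood with first-order conditional
linearization (the Lindstrom–Bates algorithm, via `nlme`), with analytic
gradients of the model function supplied for every fixed and random
effect — the spline basis is differentiated exactly, not numerically.
The spline is the textbook natural cubic basis built from B-splines with
the second-derivative boundary constraint removed by a QR projection;
interior knots sit at equally spaced quantiles of the observed
(transformed) ages and the basis continues linearly beyond the boundary
knots, which subject-specific shifts routinely cross.

If the unstructured random-effect covariance cannot be estimated the
fitter retries with a diagonal covariance, then with the intensity (and
then timing) effect dropped, recording each step in the fit log; a fit
that stops at the iteration cap is returned flagged, never silently.
Starting values come from the fixed-effects-only spline regression with
zero shifts. Reported random-effect correlations derive from the
estimated covariance matrix, not from BLUP sample correlations, which
shrinkage distorts.

Degrees of freedom are chosen by BIC over a candidate range (ties to the
smaller value). Standard errors for landmark estimates come from a
subject-level bootstrap: subjects, not records, are resampled, because
resampling records would break the within-subject correlation.

## Curves and landmarks

Velocity is the analytic first derivative of the fitted distance curve
against age. Percent velocity, $100\,d(\log y)/dt$, expresses growth as
percent of current size per year and removes scale differences between
measurements. Landmarks are extracted on a dense grid (1000 points over
the observed age range trimmed 2% at each end, to stay clear of the
linear extrapolation region): the peak is the global interior maximum,
takeoff the minimum before it, both refined by a three-point parabola
around the best grid point (accuracy of order the squared grid step).
If the maximum sits on the window edge there is no spurt and the
landmark is reported as not found — some percent-velocity curves
genuinely lack a peak. Exact ties resolve to the earliest age.

## Outlier cleaning

Records are flagged when their standardized residual (observed minus the
subject's own fitted curve, over $\sigma_r$) exceeds 4 in absolute
value — about 0.006% of Gaussian data. The fit–flag–drop cycle repeats
up to 3 times (one pass almost always suffices; the cap prevents
oscillation). The operation only excludes; a review hook lists each
flagged record with its neighbours for manual correction decisions
outside the package.

## Global-to-local stratification

To examine how curve shape depends on tempo, subjects are ranked by
their timing BLUPs and cut into nine equal groups (contiguous rank
blocks; when $n$ is not divisible by $k$ the spare subjects enlarge the
outermost groups, alternating ends; ties break by subject id). Each
group gets a local 5-d.f. model with the timing effect omitted, since
grouping has already adjusted for it. Each timing group is then split
into five subgroups by the intensity BLUPs *from its local model* (the
local estimate reflects intensity after the timing adjustment), and
second-stage local models omit both effects. Local mean curves are
compared with curves predicted from the global model at the group-mean
random effects; nine and five give a median group in each direction and
roughly equal cells.

## The synthetic-cohort generator

No public data accompany the methodology, so validation runs end to end
on simulated cohorts with known truth. The generator reads the model
forwards: random-effect triples from a trivariate normal with the SDs
and correlations reported for male height (size 6.46 cm, timing 0.86 yr,
intensity 0.13; residual SD 0.51 cm for the clinic design, 1.02 cm for
the population design), measurement schedules from one of two designs,
and Gaussian residual noise.

* The *clinic design* emulates an intensively followed cohort: staggered
  entry between 7 and 15.5 yr, follow-up windows of 1–8 yr, visits
  6-monthly but 3-monthly inside a pubertal window centred on the
  subject's own shifted APV (the schedule follows the subject), ±0.1 yr
  visit jitter, 10% missed visits. With n = 371 this yields on the order
  of ten records per subject within the open (7, 20) yr window.
* The *population design* emulates nine discrete measurement sweeps:
  annual at about 7.5–13.5 yr, then 15 and 17, ±0.25 yr within-sweep
  scatter, 68% attendance per sweep (about six visits per subject), and
  a final sweep whose ages straggle up to 20 yr, where coverage is
  sparse.

The mean curve is a sigmoid-plus-decay template (a logistic pubertal
component on top of a decaying prepubertal velocity) calibrated by
Nelder–Mead so its numerically computed landmarks hit requested targets
— size at 19, APV, PV, takeoff velocity — within 0.02 yr and 0.05 cm/yr;
calibration is done on a normalized scale so the family is exactly
linear in overall size. For mean-curve recovery studies the calibrated
template is additionally projected into the same family the model fits
(a natural spline on the centred log-age axis, knots at the quantiles of
the intended design's age distribution) and the calibration targets are
enforced on the projected curve. Without this, part of the measured
"recovery error" is just the best spline approximation of a curve
outside the spline family — a family-mismatch artefact, not an
estimation property; with it, the generative APV is a well-defined
target for the fitted curve.

The generator reproduces the visit structure, random-effect structure
and noise level of real cohort data, but not secular trends,
device-specific error structure, recruitment patterns, or real mean
curves beyond the calibrated landmarks. Passing recovery tests therefore
demonstrates correctness of the estimation machinery under the model,
not robustness to model misspecification in real data.

## Numerical choices

* Convergence: `nlme` defaults tightened to relative tolerance 1e-6,
  up to 50 outer iterations; fits are deterministic given the data.
* Landmark grid 1000 points, parabola refinement; comparison grids for
  grouped curves use 200 points over 9–19 yr (9–18 yr in validation).
* The brute-force validation oracle optimizes the joint residual sum of
  squares in O(1)-rescaled coordinates (BFGS, then Nelder–Mead, then
  BFGS); in the noise-free limit the split between a fixed effect and
  its random-effect mean is flat, so estimates are compared after
  centring each effect.
* Degenerate inputs: subjects with a single record are retained (their
  timing and intensity BLUPs shrink to zero); all-flagged cleaning data
  and empty landmark windows raise errors rather than guessing.

## Validation problem sizes

The recovery studies use n = 371 with the clinic design (five replicate
cohorts) and n = 1000 with the population design — large enough that
random-effect SDs are estimated to a few percent and the grouped
analysis has ~111 subjects per timing group and ~22 per timing-by-
intensity cell, while keeping a full validation run to minutes on one
core. The bootstrap checks use 50 replicates at n = 40 and 160.

## Known limitations

* One measurement per model: no joint multivariate fitting across
  measurements (cross-measurement structure is analysed through BLUP
  correlations and seriation of the resulting matrices).
* The residual is homoscedastic Gaussian; no serial correlation within
  subjects.
* Landmark uncertainty is bootstrap-only; no profile-likelihood
  intervals.
* Knots are placed on observation quantiles (not subject-mean-age
  quantiles); this is configurable by passing an explicit spline
  specification.
* The seriation rule is the median-correlation ranking; other seriation
  criteria would order near-ties differently.
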