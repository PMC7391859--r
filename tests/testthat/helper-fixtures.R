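## Shared fixtures, built once per test run. The small cohort keeps the
## Harpenden-style random-effect structure but at n = 60 so refits stay
## cheap; the template-family mean curve is used (no spline projection
## needed at this scale).

.fx <- new.env(parent = emptyenv())

small_truth <- function() {
  if (is.null(.fx$truth))
    .fx$truth <- true_params(
      make_mean_curve(adult_size = 174.1, target_apv = 14.2,
                      target_pv = 9.3, prepubertal_velocity = 4.8),
      size_sd = 6.46, timing_sd_yr = 0.86, intensity_sd = 0.13,
      re_corr = matrix(c(1, 0.36, 0.42,
                         0.36, 1, 0.28,
                         0.42, 0.28, 1), 3, 3),
      sigma_r = 0.51)
  .fx$truth
}

small_cohort <- function() {
  if (is.null(.fx$cohort))
    .fx$cohort <- simulate_cohort(small_truth(),
                                  harpenden_design(n = 60), seed = 42)
  .fx$cohort
}

small_fit <- function() {
  if (is.null(.fx$fit))
    .fx$fit <- fit_sitar(small_cohort()$data, df = 5)
  .fx$fit
}

## noise-free data generated directly from a spline mean curve with known
## random-effect triples; the model family is exactly specified
spline_truth_cohort <- function(re, ages = seq(7.5, 19.5, length.out = 12),
                                df = 4, sigma = 0) {
  x0 <- log(median(ages))
  xc <- log(ages) - x0
  spec <- place_knots(xc, df)
  mcv <- make_mean_curve(174.1, 14.2, 9.3, 4.8)
  cf <- qr.solve(cbind(1, build_basis(xc, spec)), mcv$value(ages))
  h <- function(u) drop(build_basis(u, spec) %*% cf[-1])
  recs <- lapply(seq_len(nrow(re)), function(i) {
    u <- (xc - re[i, 2]) * exp(re[i, 3])
    data.frame(id = sprintf("P%02d", i), age = ages,
               value = cf[1] + re[i, 1] + h(u) +
                 rnorm(length(ages), 0, sigma))
  })
  list(data = growth_data(do.call(rbind, recs)), spec = spec,
       coefs = cf, x0 = x0, re = re)
}
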