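test_that("analytic velocity matches finite differences of the distance curve", {
  fit <- small_fit()
  grid <- seq(8.5, 18.5, length.out = 200)
  v <- velocity_curve(fit, grid = grid)$value
  h <- 1e-5
  fd <- (predict(fit, grid + h) - predict(fit, grid - h)) / (2 * h)
  expect_lt(max(abs(v - fd) / pmax(abs(fd), 0.1)), 1e-5)
  ## and for an individual's curve
  re <- c(2, 0.02, 0.1)
  vi <- velocity_curve(fit, re = re, grid = grid)$value
  fdi <- (predict(fit, grid + h, re) - predict(fit, grid - h, re)) / (2 * h)
  expect_lt(max(abs(vi - fdi) / pmax(abs(fdi), 0.1)), 1e-5)
})

test_that("percent velocity is exactly 100 * velocity / value", {
  fit <- small_fit()
  grid <- seq(9, 18, length.out = 150)
  pv <- percent_velocity_curve(fit, grid = grid)$value
  v <- velocity_curve(fit, grid = grid)$value
  y <- predict(fit, grid)
  expect_equal(pv, 100 * v / y, tolerance = 1e-10)
})

test_that("landmark extraction finds peak and takeoff with refinement", {
  tt <- seq(7, 20, length.out = 1000)
  ## symmetric bump: peak exactly at 13
  bump <- curve_grid(tt, exp(-(tt - 13)^2), scale = "cm/yr")
  lm <- find_landmarks(bump)
  expect_true(lm$found_peak)
  expect_equal(lm$age_peak, 13, tolerance = 1e-3)
  expect_false(lm$found_takeoff)   # velocity rises from the window edge
  ## bump + pre-peak shoulder gives an interior takeoff
  v2 <- exp(-(tt - 13)^2) + 0.6 * exp(-((tt - 8) / 1.3)^2)
  lm2 <- find_landmarks(curve_grid(tt, v2, scale = "cm/yr"))
  expect_true(lm2$found_takeoff)
  expect_gt(lm2$age_takeoff, 8)
  expect_lt(lm2$age_takeoff, lm2$age_peak)
  expect_lte(lm2$vel_takeoff, lm2$vel_peak)
})

test_that("monotone velocity has no peak, mirroring the no-spurt case", {
  tt <- seq(7, 20, length.out = 500)
  lm <- find_landmarks(curve_grid(tt, 10 * exp(-0.2 * tt), scale = "cm/yr"))
  expect_false(lm$found_peak)
  expect_false(lm$found_takeoff)
  expect_true(is.na(lm$age_peak))
})

test_that("equal-velocity maxima resolve to the earliest age", {
  tt <- seq(7, 20, length.out = 500)
  v <- pmin(exp(-(tt - 11)^2), 0.6) + pmin(exp(-(tt - 16)^2), 0.6)
  lm <- find_landmarks(curve_grid(tt, v, scale = "cm/yr"))
  expect_lt(lm$age_peak, 12)
})

test_that("a curve built with known analytic APV is recovered by landmark search", {
  mcv <- make_mean_curve(170, 13.5, 9.5, 4.5)
  tt <- seq(7.2, 19.8, length.out = 1000)
  lm <- find_landmarks(curve_grid(tt, mcv$velocity(tt), scale = "cm/yr"))
  expect_equal(lm$age_peak, 13.5, tolerance = 0.05)
  expect_equal(lm$vel_peak, 9.5, tolerance = 0.05)
})

test_that("cm-scale and percent-scale landmark ages agree closely", {
  fit <- small_fit()
  lv <- find_landmarks(velocity_curve(fit))
  lp <- find_landmarks(percent_velocity_curve(fit))
  expect_true(lv$found_peak && lp$found_peak)
  expect_lt(abs(lv$age_peak - lp$age_peak), 0.2)
})

test_that("raising intensity compresses the spurt and raises the peak", {
  fit <- small_fit()
  grid <- seq(8.5, 18.5, length.out = 400)
  pv <- sapply(c(-0.1, 0, 0.1), function(dg)
    find_landmarks(velocity_curve(fit, re = c(0, 0, dg),
                                  grid = grid))$vel_peak)
  expect_true(all(diff(pv) > 0))
})

test_that("value_at_age equals the mean-curve prediction", {
  fit <- small_fit()
  expect_equal(value_at_age(fit, 19), predict(fit, 19))
  expect_equal(value_at_age(fit, 19), distance_curve(
    fit, grid = c(18, 19, 20))$value[2])
})

test_that("curve comparison reports max deviation and rmse", {
  tt <- seq(9, 19, length.out = 100)
  a <- curve_grid(tt, sin(tt))
  b <- curve_grid(tt, sin(tt))
  cc <- compare_curves(a, b)
  expect_equal(cc$max_abs_diff, 0)
  expect_equal(cc$rmse, 0)
  cc2 <- compare_curves(curve_grid(tt, sin(tt) + 2), b)
  expect_equal(cc2$max_abs_diff, 2)
  expect_equal(cc2$rmse, 2)
  expect_error(compare_curves(a, curve_grid(tt + 0.5, sin(tt))),
               "same age grid")
})
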