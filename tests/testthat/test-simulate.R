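test_that("mean-curve calibration hits its landmark targets", {
  mcv <- make_mean_curve(174.1, 14.2, 9.3, 4.8)
  expect_equal(mcv$landmarks$apv, 14.2, tolerance = 0.02 / 14.2)
  expect_equal(mcv$landmarks$pv, 9.3, tolerance = 0.05 / 9.3)
  expect_equal(mcv$value(19), 174.1, tolerance = 1e-6)
  expect_lt(mcv$landmarks$age_takeoff, mcv$landmarks$apv)
  ## spline-family version hits the same targets with its own landmarks
  msp <- make_mean_curve(179, 13.5, 10.6, 5, spline_df = 6)
  expect_equal(msp$landmarks$apv, 13.5, tolerance = 0.02 / 13.5)
  expect_equal(msp$landmarks$pv, 10.6, tolerance = 0.05 / 10.6)
  expect_equal(msp$value(19), 179, tolerance = 1e-6)
})

test_that("doubling adult size scales the curve and velocities exactly", {
  mA <- make_mean_curve(160, 13, 9, 4.5)
  mB <- make_mean_curve(320, 13, 18, 9)
  tt <- seq(8, 19, by = 0.5)
  expect_equal(2 * mA$value(tt), mB$value(tt), tolerance = 1e-12)
  expect_equal(2 * mA$velocity(tt), mB$velocity(tt), tolerance = 1e-12)
})

test_that("a spurtless curve has monotone-decay velocity and no peak", {
  m0 <- make_mean_curve(170, target_pv = NULL, prepubertal_velocity = 4)
  tt <- seq(7.2, 19.8, length.out = 500)
  v <- m0$velocity(tt)
  expect_true(all(diff(v) < 0))
  expect_false(find_landmarks(curve_grid(tt, v, "cm/yr"))$found_peak)
  expect_true(is.na(m0$landmarks$apv))
})

test_that("infeasible calibration targets error", {
  expect_error(make_mean_curve(170, 13, target_pv = 4,
                               prepubertal_velocity = 5), "target")
  expect_error(make_mean_curve(170, 8, 9, 4.5))
})

test_that("simulation is deterministic given the seed", {
  tr <- small_truth()
  des <- harpenden_design(n = 25)
  s1 <- simulate_cohort(tr, des, seed = 9)
  s2 <- simulate_cohort(tr, des, seed = 9)
  expect_identical(s1$data$value, s2$data$value)
  expect_identical(s1$re, s2$re)
  s3 <- simulate_cohort(tr, des, seed = 10)
  expect_false(identical(s1$data$value, s3$data$value))
})

test_that("zero random effects and zero noise lie exactly on the mean curve", {
  tr0 <- true_params(small_truth()$mean_curve, size_sd = 0,
                     timing_sd_yr = 0, intensity_sd = 0, sigma_r = 0)
  sim <- simulate_cohort(tr0, harpenden_design(n = 10), seed = 4)
  expect_equal(sim$data$value, tr0$mean_curve$value(sim$data$age),
               tolerance = 1e-12)
})

test_that("drawn random effects match the target SDs at cohort scale", {
  sim <- simulate_cohort(small_truth(), harpenden_design(n = 371), seed = 2)
  re <- sim$re
  n <- nrow(re)
  mc_tol <- 4 / sqrt(n)   # ~4 MC standard errors on a SD estimate
  expect_equal(sd(re$size), 6.46, tolerance = mc_tol)
  expect_equal(sd(re$timing) * sim$median_age, 0.86, tolerance = mc_tol)
  expect_equal(sd(re$intensity), 0.13, tolerance = mc_tol)
  expect_equal(cor(re$size, re$timing), 0.36, tolerance = 0.15)
})

test_that("the nine-sweep design yields about six visits per subject", {
  sim <- simulate_cohort(alspac_male_height_params(),
                         alspac_design(n = 400), seed = 3)
  visits <- table(sim$data$id)
  expect_gte(median(visits), 5)
  expect_lte(median(visits), 7)
  expect_true(all(sim$data$age > 7 & sim$data$age < 20))
  ## the final sweep straggles beyond age 17
  expect_gt(max(sim$data$age), 18)
})

test_that("the clinic design intensifies visits around the subject's spurt", {
  des <- harpenden_design(n = 200)
  sim <- simulate_cohort(small_truth(), des, seed = 6)
  gaps <- unlist(tapply(sim$data$age, sim$data$id,
                        function(a) diff(sort(a)), simplify = FALSE))
  ## both ~3-monthly and ~6-monthly spacings present
  expect_gt(sum(gaps < 0.4), 0.1 * length(gaps))
  expect_gt(sum(gaps > 0.4), 0.2 * length(gaps))
})
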