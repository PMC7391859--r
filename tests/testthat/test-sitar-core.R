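test_that("noise-free data from the model family are reproduced essentially exactly", {
  re <- rbind(c(3, 0.03, 0.08),
              c(-1, -0.01, -0.03),
              c(-2, -0.02, -0.05))
  gen <- spline_truth_cohort(re)
  fit <- fit_sitar(gen$data, df = 4, spec = gen$spec)
  expect_lt(fit$sigma_r, 1e-6)
  ## per-subject predictions match the data
  expect_lt(max(abs(residuals(fit))), 1e-6)
  ## BLUPs recover the true triples up to the (unidentified) mean offset
  bl <- fit$blups[match(sprintf("P%02d", 1:3), fit$blups$id), ]
  for (k in c("size", "timing", "intensity")) {
    est <- bl[[k]] - mean(bl[[k]])
    tru <- re[, match(k, c("size", "timing", "intensity"))]
    expect_equal(est, tru - mean(tru), tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("excluded random effects stay at zero and carry no variance", {
  fit <- fit_sitar(small_cohort()$data, df = 4,
                   include_effects = c("size", "intensity"))
  expect_true(all(fit$blups$timing == 0))
  expect_equal(fit$re_cov["timing", ], c(size = 0, timing = 0, intensity = 0))
  expect_gt(fit$re_cov["size", "size"], 0)
  expect_gt(fit$re_cov["intensity", "intensity"], 0)
})

test_that("the fixed-effects-only fit is the plain spline regression", {
  d <- small_cohort()$data
  fit0 <- fit_sitar(d, df = 5, include_effects = NULL)
  expect_true(fit0$converged)
  expect_equal(fit0$sigma_r, fit0$sigma_f)
  expect_equal(variance_explained(fit0), 0)
  expect_true(all(fit0$blups$size == 0))
  ## residual SD matches an independent least-squares computation
  x <- log(d$age) - log(median(d$age))
  X <- cbind(1, build_basis(x, fit0$spec))
  r <- d$value - X %*% qr.solve(X, d$value)
  expect_equal(fit0$sigma_r, sqrt(sum(r^2) / (nrow(d) - ncol(X))),
               tolerance = 1e-8)
})

test_that("prediction obeys the size and timing transformations", {
  fit <- small_fit()
  ages <- seq(9, 18, by = 0.5)
  mean_curve <- predict(fit, ages)
  ## size: a vertical shift
  expect_equal(predict(fit, ages, re = c(5, 0, 0)), mean_curve + 5,
               tolerance = 1e-10)
  ## timing: a log-age shift by log(1.05) is a 5% age delay
  shifted <- predict(fit, ages, re = c(0, log(1.05), 0))
  expect_equal(shifted, predict(fit, ages / 1.05), tolerance = 1e-8)
  ## predicting by subject id uses that subject's BLUPs
  id1 <- fit$blups$id[1]
  re1 <- unlist(fit$blups[1, c("size", "timing", "intensity")])
  expect_equal(predict(fit, ages, re = id1),
               predict(fit, ages, re = unname(re1)))
})

test_that("adding a constant to one subject moves only its size BLUP", {
  sim <- small_cohort()
  d0 <- as.data.frame(sim$data)
  fit0 <- small_fit()
  shift <- 3
  target <- d0$id[1]
  d1 <- d0
  d1$value[d1$id == target] <- d1$value[d1$id == target] + shift
  fit1 <- fit_sitar(growth_data(d1), df = 5)
  a0 <- fit0$blups$size[fit0$blups$id == target]
  a1 <- fit1$blups$size[fit1$blups$id == target]
  expect_equal(a1 - a0, shift, tolerance = 0.01 * shift * 3)
  ## mean-curve landmarks essentially unchanged
  l0 <- find_landmarks(velocity_curve(fit0))
  l1 <- find_landmarks(velocity_curve(fit1))
  expect_equal(l1$age_peak, l0$age_peak, tolerance = 0.01 * shift)
  expect_equal(l1$vel_peak, l0$vel_peak, tolerance = 0.01 * shift)
})

test_that("a subject with a single record has its timing BLUP shrunk to zero", {
  sim <- small_cohort()
  d <- as.data.frame(sim$data)
  lone <- data.frame(id = "LONE", age = 12.3, value = 150)
  fit <- fit_sitar(growth_data(rbind(d, lone)), df = 4)
  bl <- fit$blups[fit$blups$id == "LONE", ]
  sds <- re_sds(fit)
  ## a single record carries no timing information: the BLUP shrinks to
  ## (essentially) zero, far inside the population SD; intensity is only
  ## bounded by its SD since correlation with size pulls it slightly
  expect_lt(abs(bl$timing), 0.1 * sds["timing"])
  expect_lt(abs(bl$intensity), sds["intensity"])
})

test_that("standardized residuals flag an injected error as the extreme record", {
  sim <- small_cohort()
  d <- as.data.frame(sim$data)
  k <- 17
  fit0 <- small_fit()
  d$value[k] <- d$value[k] + 10 * fit0$sigma_r
  fit <- fit_sitar(growth_data(d), df = 5)
  z <- standardized_residuals(fit)
  expect_equal(which.max(abs(z)), k)
  expect_gt(abs(z[k]), 4)
})

test_that("variance explained falls as generative noise rises", {
  tr <- small_truth()
  des <- harpenden_design(n = 60)
  noisy <- true_params(tr$mean_curve, tr$size_sd, tr$timing_sd_yr,
                       tr$intensity_sd, tr$re_corr, sigma_r = 1.6)
  f1 <- small_fit()
  f2 <- fit_sitar(simulate_cohort(noisy, des, seed = 42)$data, df = 5)
  v1 <- variance_explained(f1)
  v2 <- variance_explained(f2)
  expect_gt(v1, 98)
  expect_lt(v2, v1)
})

test_that("timing SD conversion multiplies by median age only under log age", {
  fit <- small_fit()
  expect_equal(timing_sd_years(fit),
               sqrt(fit$re_cov["timing", "timing"]) * median(fit$data$age),
               ignore_attr = TRUE)
  fit_lin <- fit_sitar(small_cohort()$data, df = 4, use_log_age = FALSE)
  expect_equal(timing_sd_years(fit_lin),
               sqrt(fit_lin$re_cov["timing", "timing"]),
               ignore_attr = TRUE)
})
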