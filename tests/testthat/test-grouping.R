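test_that("equal-size splitting handles remainders at the extremes", {
  ## 5227 subjects into 9 groups: sizes 581 x 7 and 580 x 2
  fit <- small_fit()
  fake <- fit
  n <- 5227
  fake$blups <- data.frame(id = sprintf("Z%05d", 1:n),
                           size = 0, timing = rnorm(n), intensity = 0)
  asg <- split_by_blup(fake, "timing", 9)
  sizes <- table(asg$subjects$group)
  expect_equal(sort(unique(as.integer(sizes))), c(580, 581))
  expect_equal(sum(sizes == 581), 7)
  expect_lte(diff(range(sizes)), 1)
  ## groups ordered by ascending BLUP
  expect_true(all(diff(asg$group_means$timing) > 0))
  bnd <- tapply(asg$subjects$blup, asg$subjects$group, max)
  expect_true(all(diff(bnd) > 0))
})

test_that("equal-size constraint holds across n and k", {
  fit <- small_fit()
  fake <- fit
  for (n in c(47, 100, 5183)) {
    fake$blups <- data.frame(id = sprintf("Z%05d", 1:n), size = 0,
                             timing = seq_len(n) / n, intensity = 0)
    for (k in c(2, 5, 9)) {
      asg <- split_by_blup(fake, "timing", k)
      expect_lte(diff(range(table(asg$subjects$group))), 1)
    }
  }
})

test_that("k = 1 yields a single group with near-zero mean random effects", {
  fit <- small_fit()
  asg <- split_by_blup(fit, "timing", 1)
  expect_equal(nrow(asg$group_means), 1)
  expect_equal(asg$group_means$n, fit$n)
  sds <- re_sds(fit)
  expect_lt(abs(asg$group_means$timing), 0.2 * sds["timing"])
  expect_lt(abs(asg$group_means$size), 0.2 * sds["size"])
})

test_that("k above the number of subjects errors; ties split deterministically", {
  fit <- small_fit()
  expect_error(split_by_blup(fit, "timing", fit$n + 1), "exceeds")
  fake <- fit
  fake$blups <- data.frame(id = c("B", "A", "D", "C"), size = 0,
                           timing = c(1, 1, 2, 2), intensity = 0)
  a1 <- split_by_blup(fake, "timing", 2)
  expect_equal(a1$subjects$id, c("A", "B", "C", "D"))
})

test_that("groups are ordered by the generative timing truth", {
  sim <- small_cohort()
  fit <- small_fit()
  asg <- split_by_blup(fit, "timing", 4)
  m <- merge(asg$subjects, sim$re, by = "id")
  true_means <- tapply(m$timing, m$group, mean)
  expect_true(all(diff(true_means) > 0))
})

test_that("a whole-cohort 'local' fit with nothing omitted matches the global fit", {
  d <- small_cohort()$data
  fit <- small_fit()
  asg <- split_by_blup(fit, "timing", 1)
  lf <- fit_local_models(d, asg, df = 5, omit_effects = character(0))
  expect_length(lf, 1)
  expect_equal(lf[[1]]$loglik, fit$loglik, tolerance = 1e-4)
})

test_that("local fits omit the conditioned-on effects", {
  d <- small_cohort()$data
  fit <- small_fit()
  asg <- split_by_blup(fit, "timing", 2)
  lf <- fit_local_models(d, asg, df = 4, omit_effects = "timing")
  for (f in lf) {
    expect_false("timing" %in% f$include_effects)
    expect_true(all(f$blups$timing == 0))
  }
})

test_that("global prediction for a group applies its mean random effects", {
  fit <- small_fit()
  asg <- split_by_blup(fit, "timing", 4)
  grid <- seq(9, 19, length.out = 200)
  ## a synthetic group with zero mean effects reproduces the mean curve
  asg0 <- asg
  asg0$group_means[1, c("size", "timing", "intensity")] <- 0
  p0 <- predict_group_from_global(fit, asg0, 1, grid = grid)
  expect_equal(p0$value, predict(fit, grid), tolerance = 1e-12)
  ## the earliest-timing group peaks before the latest
  v1 <- predict_group_from_global(fit, asg, 1, grid = grid,
                                  what = "velocity")
  v4 <- predict_group_from_global(fit, asg, 4, grid = grid,
                                  what = "velocity")
  a1 <- find_landmarks(v1)$age_peak
  a4 <- find_landmarks(v4)$age_peak
  expect_lt(a1, a4)
})
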