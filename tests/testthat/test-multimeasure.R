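## builds two "fits" that carry only the BLUP tables the correlation
## machinery uses
fake_fit <- function(ids, size, timing = 0, intensity = 0) {
  f <- small_fit()
  f$blups <- data.frame(id = ids, size = size, timing = timing,
                        intensity = intensity)
  f
}

test_that("a measurement correlates perfectly with itself", {
  fit <- small_fit()
  m <- cross_measure_correlations(list(height = fit, again = fit), "size")
  expect_equal(unclass(m)["height", "again"], 1)
  expect_equal(diag(unclass(m)), c(height = 1, again = 1))
})

test_that("generative cross-measurement size correlation is recovered", {
  set.seed(31)
  n <- 300
  rho <- 0.8
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  ids <- sprintf("S%03d", 1:n)
  ## BLUP-level construction: correlation machinery operates on the
  ## per-subject effect estimates shared across fits
  f1 <- fake_fit(ids, size = 6 * z1)
  f2 <- fake_fit(ids, size = 3 * z2)
  m <- cross_measure_correlations(list(height = f1, leg = f2), "size")
  expect_equal(unclass(m)["height", "leg"], rho, tolerance = 0.1)
  expect_equal(attr(m, "n")["height", "leg"], n, ignore_attr = TRUE)
})

test_that("correlations use shared subjects and mark sparse pairs missing", {
  f1 <- fake_fit(sprintf("A%02d", 1:20), size = rnorm(20))
  f2 <- fake_fit(sprintf("A%02d", 11:30), size = rnorm(20))
  m <- cross_measure_correlations(list(x = f1, y = f2), "size")
  expect_equal(attr(m, "n")["x", "y"], 10, ignore_attr = TRUE)
  f3 <- fake_fit(sprintf("B%02d", 1:20), size = rnorm(20))
  m2 <- cross_measure_correlations(list(x = f1, y = f3), "size")
  expect_true(is.na(unclass(m2)["x", "y"]))
  expect_error(seriate_measures(m2), "missing")
})

test_that("correlations are invariant to shifting one measurement's BLUPs", {
  set.seed(8)
  ids <- sprintf("S%02d", 1:50)
  a <- rnorm(50); b <- 0.6 * a + rnorm(50, 0, 0.5)
  m1 <- cross_measure_correlations(list(x = fake_fit(ids, a),
                                        y = fake_fit(ids, b)), "size")
  m2 <- cross_measure_correlations(list(x = fake_fit(ids, a),
                                        y = fake_fit(ids, b + 100)), "size")
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-12)
})

test_that("seriation ranks by median correlation and permutes entries", {
  nm <- c("ht", "leg", "sit", "arm")
  m <- diag(1, 4); dimnames(m) <- list(nm, nm)
  ## ht-leg strongly coupled; arm weakly coupled to everything
  m["ht", "leg"] <- m["leg", "ht"] <- 0.9
  m["ht", "sit"] <- m["sit", "ht"] <- 0.5
  m["leg", "sit"] <- m["sit", "leg"] <- 0.45
  m["ht", "arm"] <- m["arm", "ht"] <- 0.1
  m["leg", "arm"] <- m["arm", "leg"] <- 0.12
  m["sit", "arm"] <- m["arm", "sit"] <- 0.05
  s <- seriate_measures(m)
  expect_equal(abs(which(s$order == "ht") - which(s$order == "leg")),
               1L)                          # the coupled pair is adjacent
  expect_equal(s$order[4], "arm")           # weakest last
  ## pure permutation: multiset of entries unchanged
  expect_equal(sort(as.vector(s$matrix)), sort(as.vector(m)))

  ## block-diagonal matrix: the larger coupled block (whose members'
  ## median correlations are positive) comes out contiguous and first
  nm5 <- c("ht", "leg", "sit", "arm", "thigh")
  b <- diag(1, 5); dimnames(b) <- list(nm5, nm5)
  b[1:3, 1:3] <- 0.8; b[4:5, 4:5] <- 0.6; diag(b) <- 1
  s2 <- seriate_measures(b)
  expect_setequal(s2$order[1:3], c("ht", "leg", "sit"))
  expect_setequal(s2$order[4:5], c("arm", "thigh"))

  ## 2x2: order fixed by the deterministic tie rule (names)
  m2 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("b", "a"),
                                                     c("b", "a")))
  expect_equal(seriate_measures(m2)$order, c("a", "b"))
})

test_that("size percent SD divides the size SD by size at 19", {
  fit <- small_fit()
  expect_equal(size_percent_sd(fit),
               100 * sqrt(fit$re_cov["size", "size"]) / value_at_age(fit, 19),
               ignore_attr = TRUE)
  ## at the generative values this lands near the familiar ~3.7%
  expect_gt(size_percent_sd(fit), 2.5)
  expect_lt(size_percent_sd(fit), 5)
})
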