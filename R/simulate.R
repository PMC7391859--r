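## Synthetic-cohort generator. The generative model is exactly the fitted
## one read forwards: y = alpha + m[pivoted (log-)age shifted by beta and
## scaled by exp(gamma)] + Gaussian noise, with (alpha, beta, gamma)
## trivariate normal. The mean curve m comes from a sigmoid-plus-decay
## template calibrated to requested landmarks.

## Template: double-logistic distance curve (adult size minus a mixture of
## a slow pre-pubertal decay and a sharp pubertal sigmoid), whose velocity
## is a decaying baseline plus a pubertal bump. Calibration is done on a
## normalized scale (size at 19 = 1) so the family is exactly linear in
## overall size.
.template_value <- function(t, p) {
  ## p: h1, d (= h1 - h_theta), s0, s1, theta
  p$h1 - 2 * p$d / (exp(p$s0 * (t - p$theta)) + exp(p$s1 * (t - p$theta)))
}
.template_velocity <- function(t, p) {
  e0 <- exp(p$s0 * (t - p$theta)); e1 <- exp(p$s1 * (t - p$theta))
  2 * p$d * (p$s0 * e0 + p$s1 * e1) / (e0 + e1)^2
}

## landmark extraction for the template, independent of the fitted-curve
## machinery: dense grid bracketing + 1-d optimize
.template_landmarks <- function(p, window = c(7.2, 19.8)) {
  tt <- seq(window[1], window[2], length.out = 2000L)
  v <- .template_velocity(tt, p)
  i <- which.max(v)
  out <- list(apv = NA_real_, pv = NA_real_,
              age_takeoff = NA_real_, vel_takeoff = NA_real_)
  if (i == 1L || i == length(tt)) return(out)
  o <- stats::optimize(.template_velocity, c(tt[i - 1], tt[i + 1]), p = p,
                       maximum = TRUE, tol = 1e-8)
  out$apv <- o$maximum; out$pv <- o$objective
  j <- which.min(v[1:(i - 1L)])
  if (j > 1L) {
    o2 <- stats::optimize(.template_velocity, c(tt[j - 1], tt[j + 1]), p = p,
                          tol = 1e-8)
    out$age_takeoff <- o2$minimum; out$vel_takeoff <- o2$objective
  } else {
    out$age_takeoff <- tt[1]; out$vel_takeoff <- v[1]
  }
  out
}

## landmarks of a natural-spline distance curve on the log-age axis
.spline_curve_landmarks <- function(spec, coefs, x0, window = c(7.2, 19.8)) {
  vfun <- function(t)
    drop(basis_derivative(log(t) - x0, spec) %*% coefs[-1]) / t
  tt <- seq(window[1], window[2], length.out = 2000L)
  v <- vfun(tt)
  i <- which.max(v)
  out <- list(apv = NA_real_, pv = NA_real_,
              age_takeoff = NA_real_, vel_takeoff = NA_real_)
  if (i == 1L || i == length(tt)) return(out)
  o <- stats::optimize(vfun, c(tt[i - 1], tt[i + 1]), maximum = TRUE,
                       tol = 1e-8)
  out$apv <- o$maximum; out$pv <- o$objective
  j <- which.min(v[1:(i - 1L)])
  if (j > 1L) {
    o2 <- stats::optimize(vfun, c(tt[j - 1], tt[j + 1]), tol = 1e-8)
    out$age_takeoff <- o2$minimum; out$vel_takeoff <- o2$objective
  } else {
    out$age_takeoff <- tt[1]; out$vel_takeoff <- v[1]
  }
  out
}

#' Construct a smooth mean growth curve with known landmarks
#'
#' Builds a parametric distance curve (years to cm) from a
#' sigmoid-plus-decay template and calibrates it so that its numerically
#' computed landmarks match the requested targets: size at age 19, age at
#' peak velocity, peak velocity, and the takeoff (pre-peak minimum)
#' velocity. The calibrated landmarks are stored with the curve, so
#' simulated cohorts carry analytic ground truth for recovery tests.
#'
#' With \code{spline_df} set, the calibrated curve is expressed in the
#' same family the model fits — a natural cubic spline on the centred
#' log-age axis, with knots at quantiles of \code{knot_ages} — and the
#' calibration targets are enforced on the spline curve itself. This
#' makes mean-curve recovery well defined: a fitted model of the same
#' d.f. can represent the generative curve (near-)exactly, so landmark
#' recovery error reflects estimation, not family mismatch. Supply the
#' intended visit design's age distribution via [design_age_sample()].
#'
#' With \code{target_pv = NULL} the pubertal component is removed
#' (velocity decays monotonically; no interior peak), for degenerate-case
#' testing.
#'
#' @param adult_size size at age 19 (cm).
#' @param target_apv age at peak velocity (years, in (9, 16)).
#' @param target_pv peak velocity (cm/yr), greater than
#'   \code{prepubertal_velocity}; or \code{NULL} for a spurtless curve.
#' @param prepubertal_velocity velocity at takeoff (cm/yr).
#' @param spline_df if non-NULL, express the curve as a natural spline of
#'   this many degrees of freedom on the log-age axis.
#' @param knot_ages age sample whose quantiles place the spline knots
#'   (default: a log-uniform grid over 7.3-19.7 yr).
#' @return An object of class \code{"mean_curve"}: list with \code{value}
#'   and \code{velocity} functions of age, the curve parameters and the
#'   calibrated \code{landmarks}.
#' @export
make_mean_curve <- function(adult_size = 174.1, target_apv = 14.2,
                            target_pv = 9.3, prepubertal_velocity = 4.8,
                            spline_df = NULL, knot_ages = NULL) {
  stopifnot(adult_size > 0, prepubertal_velocity > 0)
  if (is.null(target_pv)) {
    ## spurtless branch: s1 = s0 collapses the template to
    ## value = h1 - d exp(-s0 (t - theta)), a pure exponential-decay
    ## velocity with no interior peak
    s0 <- 0.15
    theta <- 19
    vref <- prepubertal_velocity / adult_size
    d <- vref * exp(s0 * (10 - theta)) / s0   # velocity at age 10 = target
    p <- list(h1 = 1 + d, d = d, s0 = s0, s1 = s0, theta = theta)
    cal <- list(apv = NA_real_, pv = NA_real_, age_takeoff = NA_real_,
                vel_takeoff = NA_real_)
    return(.finish_mean_curve(p, adult_size, cal))
  }
  stopifnot(target_apv > 9, target_apv < 16, target_pv > prepubertal_velocity)
  ## normalized targets (size at 19 = 1)
  tg <- c(apv = target_apv, pv = target_pv / adult_size,
          vto = prepubertal_velocity / adult_size)

  if (!is.null(spline_df)) {
    if (is.null(knot_ages))
      knot_ages <- exp(seq(log(7.3), log(19.7), length.out = 400L))
    x0 <- log(stats::median(knot_ages))
    xr <- log(knot_ages) - x0
    spec <- place_knots(xr, spline_df)
    X <- cbind(1, build_basis(xr, spec))
    X19 <- cbind(1, build_basis(log(19) - x0, spec))
    project <- function(p) {
      cf <- qr.solve(X, .template_value(knot_ages, p))
      cf / drop(X19 %*% cf)              # pin spline value at 19 to 1
    }
    measure <- function(cf) .spline_curve_landmarks(spec, cf, x0)
  } else {
    project <- function(p) p
    measure <- function(p) .template_landmarks(p)
  }

  obj <- function(par) {
    p <- list(h1 = 1, d = exp(par[1]), s0 = exp(par[2]),
              s1 = exp(par[2]) + exp(par[3]), theta = par[4])
    p$h1 <- 1 + (1 - .template_value(19, p))   # pin value at 19 to 1
    lm <- measure(project(p))
    if (!is.finite(lm$apv)) return(1e6)
    ((lm$apv - tg["apv"]) / tg["apv"])^2 +
      ((lm$pv - tg["pv"]) / tg["pv"])^2 +
      ((lm$vel_takeoff - tg["vto"]) / tg["vto"])^2
  }
  init <- c(log(0.067), log(0.11), log(1.13), target_apv + 0.4)
  opt <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  par <- opt$par
  p <- list(h1 = 1, d = exp(par[1]), s0 = exp(par[2]),
            s1 = exp(par[2]) + exp(par[3]), theta = par[4])
  p$h1 <- 1 + (1 - .template_value(19, p))
  fitted_obj <- project(p)
  cal <- measure(fitted_obj)
  if (abs(cal$apv - tg["apv"]) > 0.02 ||
      abs(cal$pv - tg["pv"]) * adult_size > 0.05)
    stop("infeasible target combination: calibration reached APV ",
         round(cal$apv, 3), ", PV ", round(cal$pv * adult_size, 3))
  if (!is.null(spline_df))
    .finish_spline_curve(spec, fitted_obj, x0, adult_size, cal)
  else
    .finish_mean_curve(p, adult_size, cal)
}

.finish_spline_curve <- function(spec, coefs, x0, adult_size, cal) {
  value <- function(t)
    adult_size * drop(cbind(1, build_basis(log(t) - x0, spec)) %*% coefs)
  velocity <- function(t)
    adult_size * drop(basis_derivative(log(t) - x0, spec) %*% coefs[-1]) / t
  structure(list(
    value = value, velocity = velocity,
    params = list(spec = spec, coefs = coefs, x0 = x0),
    adult_size = adult_size,
    landmarks = list(apv = cal$apv,
                     pv = if (is.finite(cal$pv)) cal$pv * adult_size else NA_real_,
                     age_takeoff = cal$age_takeoff,
                     vel_takeoff = if (is.finite(cal$vel_takeoff))
                       cal$vel_takeoff * adult_size else NA_real_)),
    class = "mean_curve")
}

#' Representative observation-age sample for a visit design
#'
#' Generates the visit schedules of a cohort under the design (no
#' measurement values) and returns the pooled ages. Useful for placing
#' generative spline knots at the same quantiles a model fitted to such a
#' cohort would use.
#'
#' @param design a [harpenden_design()] / [alspac_design()] object.
#' @param seed integer seed for the schedule randomness.
#' @return Numeric vector of ages (years).
#' @export
design_age_sample <- function(design, seed = 1000L) {
  stopifnot(inherits(design, "design_spec"))
  set.seed(seed)
  unlist(lapply(seq_len(design$n), function(i)
    .visit_ages(design, apv_i = 13.5)))
}

.finish_mean_curve <- function(p, adult_size, cal) {
  value <- function(t) adult_size * .template_value(t, p)
  velocity <- function(t) adult_size * .template_velocity(t, p)
  structure(list(
    value = value, velocity = velocity, params = p,
    adult_size = adult_size,
    landmarks = list(apv = cal$apv,
                     pv = if (is.finite(cal$pv)) cal$pv * adult_size else NA_real_,
                     age_takeoff = cal$age_takeoff,
                     vel_takeoff = if (is.finite(cal$vel_takeoff))
                       cal$vel_takeoff * adult_size else NA_real_)),
    class = "mean_curve")
}

#' @export
print.mean_curve <- function(x, ...) {
  cat("Mean growth curve: size at 19 =", format(x$value(19), digits = 5),
      "cm\n")
  lm <- x$landmarks
  if (is.finite(lm$apv))
    cat("  APV", format(lm$apv, digits = 4), "yr, PV",
        format(lm$pv, digits = 3), "cm/yr; takeoff",
        format(lm$vel_takeoff, digits = 3), "cm/yr at",
        format(lm$age_takeoff, digits = 4), "yr\n")
  else cat("  no pubertal spurt (monotone-decay velocity)\n")
  invisible(x)
}

#' Generative parameters for a synthetic cohort
#'
#' @param mean_curve a [make_mean_curve()] object.
#' @param size_sd SD of the size random effect (cm).
#' @param timing_sd_yr SD of the timing random effect in years (converted
#'   internally to the log-age axis via the design's median age).
#' @param intensity_sd SD of the intensity random effect (dimensionless).
#' @param re_corr 3x3 correlation matrix (size, timing, intensity order).
#' @param sigma_r residual SD (cm).
#' @param use_log_age logical; generate on the log-age axis (default),
#'   matching the fitted model.
#' @return An object of class \code{"true_params"}.
#' @export
true_params <- function(mean_curve, size_sd, timing_sd_yr, intensity_sd,
                        re_corr = diag(3), sigma_r, use_log_age = TRUE) {
  stopifnot(inherits(mean_curve, "mean_curve"),
            size_sd >= 0, timing_sd_yr >= 0, intensity_sd >= 0, sigma_r >= 0)
  re_corr <- as.matrix(re_corr)
  stopifnot(nrow(re_corr) == 3L, ncol(re_corr) == 3L,
            all(abs(re_corr - t(re_corr)) < 1e-12))
  if (min(eigen(re_corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("re_corr is not positive semidefinite")
  structure(list(mean_curve = mean_curve, size_sd = size_sd,
                 timing_sd_yr = timing_sd_yr, intensity_sd = intensity_sd,
                 re_corr = re_corr, sigma_r = sigma_r,
                 use_log_age = isTRUE(use_log_age)),
            class = "true_params")
}

#' Harpenden-style male height generative truth
#'
#' Random-effect SDs and correlations, residual SD and mean-curve
#' landmarks set to the male height estimates of the reference pubertal
#' growth analysis (size SD 6.46 cm, timing SD 0.86 yr, intensity SD 0.13,
#' residual SD 0.51 cm; mean curve with APV 14.2 yr, PV 9.3 cm/yr, takeoff
#' 4.8 cm/yr, 174.1 cm at age 19).
#'
#' @return A [true_params()] object.
#' @export
harpenden_male_height_params <- function() {
  true_params(
    make_mean_curve(adult_size = 174.1, target_apv = 14.2,
                    target_pv = 9.3, prepubertal_velocity = 4.8,
                    spline_df = 7L,
                    knot_ages = design_age_sample(harpenden_design())),
    size_sd = 6.46, timing_sd_yr = 0.86, intensity_sd = 0.13,
    re_corr = matrix(c(1, 0.36, 0.42,
                       0.36, 1, 0.28,
                       0.42, 0.28, 1), 3, 3),
    sigma_r = 0.51)
}

#' ALSPAC-style boys height generative truth
#'
#' Mean curve calibrated to the boys' APV of 13.5 yr and PV 10.6 cm/yr
#' with 179 cm at age 19; timing SD 0.8 yr, intensity SD 0.12, size SD
#' 6 cm, residual SD 1.02 cm.
#'
#' @return A [true_params()] object.
#' @export
alspac_male_height_params <- function() {
  true_params(
    make_mean_curve(adult_size = 179, target_apv = 13.5,
                    target_pv = 10.6, prepubertal_velocity = 5,
                    spline_df = 6L,
                    knot_ages = design_age_sample(alspac_design(n = 500))),
    size_sd = 6.0, timing_sd_yr = 0.8, intensity_sd = 0.12,
    re_corr = matrix(c(1, 0.36, 0.42,
                       0.36, 1, 0.28,
                       0.42, 0.28, 1), 3, 3),
    sigma_r = 1.02)
}

#' Visit-schedule designs
#'
#' \code{harpenden_design()} emulates an intensively followed clinic
#' cohort: subjects enter at varying ages and are measured 6-monthly,
#' switching to 3-monthly inside a subject-specific pubertal window
#' centred on that subject's (shifted) age at peak velocity. Follow-up
#' windows are staggered so the records-per-subject distribution matches a
#' cohort of about ten visits per child.
#'
#' \code{alspac_design()} emulates a population cohort measured in nine
#' discrete sweeps: annually from about 7.5 to 13.5 years, then at 15 and
#' 17, with per-visit age scatter, partial attendance, and a final sweep
#' whose ages straggle up to age 20.
#'
#' @param n number of subjects.
#' @param age_window open age interval retained, default (7, 20).
#' @param dropout per-visit probability of a missed measurement
#'   (Harpenden) — attendance per sweep for ALSPAC is \code{attendance}.
#' @param entry_range ages between which subjects enter follow-up.
#' @param follow_up range of per-subject follow-up durations (years).
#' @param jitter half-width of uniform visit-age jitter (years).
#' @param sweeps nominal sweep ages (ALSPAC).
#' @param attendance per-sweep attendance probability (ALSPAC).
#' @return An object of class \code{"design_spec"}.
#' @export
harpenden_design <- function(n = 371, age_window = c(7, 20),
                             entry_range = c(7, 15.5), follow_up = c(1, 8),
                             dropout = 0.1, jitter = 0.1) {
  structure(list(type = "harpenden", n = n, age_window = age_window,
                 entry_range = entry_range, follow_up = follow_up,
                 dropout = dropout, jitter = jitter),
            class = "design_spec")
}

#' @rdname harpenden_design
#' @export
alspac_design <- function(n = 5227, age_window = c(7, 20),
                          sweeps = c(7.5, 8.5, 9.5, 10.5, 11.5, 12.5,
                                     13.5, 15, 17),
                          attendance = 0.68, jitter = 0.25) {
  structure(list(type = "alspac", n = n, age_window = age_window,
                 sweeps = sweeps, attendance = attendance, jitter = jitter),
            class = "design_spec")
}

## visit ages for one subject; apv_i centres the Harpenden pubertal window
.visit_ages <- function(design, apv_i) {
  w <- design$age_window
  if (design$type == "harpenden") {
    entry <- stats::runif(1, design$entry_range[1], design$entry_range[2])
    exit <- min(entry + stats::runif(1, design$follow_up[1],
                                     design$follow_up[2]), w[2] - 0.05)
    ages <- numeric(0); a <- entry
    while (a < exit) {
      ages <- c(ages, a)
      a <- a + if (a > apv_i - 2.5 && a < apv_i + 1) 0.25 else 0.5
    }
    ages <- ages + stats::runif(length(ages), -design$jitter, design$jitter)
    keep <- stats::runif(length(ages)) > design$dropout
    ages <- ages[keep]
  } else if (design$type == "alspac") {
    attend <- stats::runif(length(design$sweeps)) < design$attendance
    ages <- design$sweeps[attend]
    if (length(ages)) {
      j <- stats::runif(length(ages), -design$jitter, design$jitter)
      ## final sweep straggles: ages spread from the sweep age up to ~20
      last <- ages == design$sweeps[length(design$sweeps)]
      j[last] <- stats::runif(sum(last), 0, 2.8)
      ages <- ages + j
    }
  } else stop("unknown design type ", design$type)
  ages <- sort(ages[ages > w[1] & ages < w[2]])
  if (!length(ages)) ages <- stats::runif(1, w[1] + 0.5, w[2] - 0.5)
  ages
}

#' Simulate a longitudinal growth cohort
#'
#' Draws per-subject random-effect triples from the trivariate normal with
#' the requested SDs and correlations, generates visit schedules from the
#' design, and produces measurements from the shape-invariant model
#' \code{y = alpha + m[pivot + (x - pivot - beta) exp(gamma)] + e} on the
#' (log-) age axis, where the pivot is the log of the cohort's median
#' observation age — the same convention the fitter uses, so generative
#' and fitted parameters coincide. The timing SD is specified in years and
#' converted to the log-age axis by dividing by the median age.
#'
#' @param truth a [true_params()] object.
#' @param design a [harpenden_design()] / [alspac_design()] object.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return List with \code{data} (a [growth_data()]), \code{re} (data
#'   frame of true per-subject size/timing/intensity effects; timing on
#'   the working axis), \code{truth}, \code{design}, \code{median_age} and
#'   the axis \code{pivot}.
#' @export
simulate_cohort <- function(truth, design, seed = 1L) {
  stopifnot(inherits(truth, "true_params"), inherits(design, "design_spec"))
  set.seed(seed)
  n <- design$n
  L <- chol(truth$re_corr)
  Z <- matrix(stats::rnorm(3L * n), n, 3L) %*% L   # unit-SD correlated
  apv0 <- truth$mean_curve$landmarks$apv
  if (!is.finite(apv0)) apv0 <- 12.5               # spurtless: nominal centre
  apv_i <- apv0 + Z[, 2] * truth$timing_sd_yr      # for window centring only
  ages <- lapply(seq_len(n), function(i) .visit_ages(design, apv_i[i]))
  med <- stats::median(unlist(ages))
  sd_beta <- if (truth$use_log_age) truth$timing_sd_yr / med
             else truth$timing_sd_yr
  alpha <- Z[, 1] * truth$size_sd
  beta <- Z[, 2] * sd_beta
  gamma <- Z[, 3] * truth$intensity_sd
  pivot <- if (truth$use_log_age) log(med) else med
  m <- truth$mean_curve$value
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    t_i <- ages[[i]]
    if (truth$use_log_age) {
      u <- pivot + (log(t_i) - pivot - beta[i]) * exp(gamma[i])
      mu <- alpha[i] + m(exp(u))
    } else {
      u <- pivot + (t_i - pivot - beta[i]) * exp(gamma[i])
      mu <- alpha[i] + m(u)
    }
    recs[[i]] <- data.frame(
      id = sprintf("S%04d", i), age = t_i,
      value = mu + stats::rnorm(length(t_i), 0, truth$sigma_r),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  list(data = growth_data(df, measure = "synthetic height", sex = "male"),
       re = data.frame(id = sprintf("S%04d", seq_len(n)), size = alpha,
                       timing = beta, intensity = gamma,
                       stringsAsFactors = FALSE),
       truth = truth, design = design, median_age = med, pivot = pivot)
}
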