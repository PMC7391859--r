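#' Curve on a dense age grid
#'
#' A two-column data frame (\code{age}, \code{value}) with a scale tag:
#' \code{"cm"} for distance curves, \code{"cm/yr"} for velocity and
#' \code{"\%/yr"} for percent velocity.
#'
#' @param age strictly increasing numeric grid (years).
#' @param value numeric curve values.
#' @param scale scale tag string.
#' @return A data frame of class \code{"curve_grid"}.
#' @export
curve_grid <- function(age, value, scale = "cm") {
  if (is.unsorted(age, strictly = TRUE))
    stop("age grid must be strictly increasing")
  structure(data.frame(age = age, value = value),
            scale = scale, class = c("curve_grid", "data.frame"))
}

.default_grid <- function(fit, n = 1000L, trim = 0.02) {
  rng <- range(fit$data$age)
  span <- diff(rng)
  seq(rng[1] + trim * span, rng[2] - trim * span, length.out = n)
}

#' Distance curve (size against age)
#'
#' @param fit a [fit_sitar()] object.
#' @param re random-effect triple, default the mean curve.
#' @param grid ages (years); default 1000 points over the observed range
#'   trimmed 2\% at each end to avoid boundary extrapolation artefacts.
#' @return A [curve_grid()] in cm.
#' @export
distance_curve <- function(fit, re = c(0, 0, 0), grid = .default_grid(fit)) {
  curve_grid(grid, predict(fit, grid, re = re), scale = "cm")
}

#' Velocity curve (first derivative of the distance curve)
#'
#' Uses the analytic spline derivative. Under log age the chain rule gives
#' \code{dy/dt = (dy/dx) / t} with \code{x = log t}.
#'
#' @inheritParams distance_curve
#' @return A [curve_grid()] in cm/yr.
#' @export
velocity_curve <- function(fit, re = c(0, 0, 0), grid = .default_grid(fit)) {
  stopifnot(inherits(fit, "sitar_fit"), length(re) == 3L)
  x <- (if (fit$use_log_age) log(grid) else grid) - fit$xoffset
  scale <- exp(fit$gamma0 + re[3])
  u <- (x - fit$beta0 - re[2]) * scale
  dydx <- drop(basis_derivative(u, fit$spec) %*% fit$coefficients$spline) * scale
  v <- if (fit$use_log_age) dydx / grid else dydx
  curve_grid(grid, v, scale = "cm/yr")
}

#' Percent velocity curve
#'
#' Velocity as percent of current size per year,
#' \code{100 d(log y)/dt = 100 * velocity / value}, the slope of the
#' distance curve drawn on a 100 x natural-log scale. It removes scale
#' differences between measurements.
#'
#' @inheritParams distance_curve
#' @return A [curve_grid()] in \%/yr.
#' @export
percent_velocity_curve <- function(fit, re = c(0, 0, 0),
                                   grid = .default_grid(fit)) {
  dist <- distance_curve(fit, re, grid)
  if (any(dist$value <= 0))
    stop("mean curve must be positive to compute percent velocity")
  vel <- velocity_curve(fit, re, grid)
  curve_grid(grid, 100 * vel$value / dist$value, scale = "%/yr")
}

#' Mean-curve value at a given age
#'
#' @param fit a [fit_sitar()] object.
#' @param age age in years (may lie slightly beyond the boundary knots,
#'   where the curve continues linearly).
#' @return Value in cm.
#' @export
value_at_age <- function(fit, age) {
  predict(fit, age, re = c(0, 0, 0))
}

## three-point parabola refinement around grid index i
.parabola_refine <- function(age, value, i) {
  if (i <= 1L || i >= length(age)) return(c(age[i], value[i]))
  y1 <- value[i - 1L]; y2 <- value[i]; y3 <- value[i + 1L]
  d1 <- (y3 - y1) / 2
  d2 <- y1 - 2 * y2 + y3
  if (d2 == 0 || abs(d1 / d2) > 1) return(c(age[i], value[i]))
  h <- (age[i + 1L] - age[i - 1L]) / 2  # assumes locally uniform grid
  c(age[i] - d1 / d2 * h, y2 - d1^2 / (2 * d2))
}

#' Extract takeoff and peak landmarks from a velocity curve
#'
#' The peak is the global interior maximum of velocity on the search
#' window; takeoff is the velocity minimum prior to the peak. Both are
#' refined by local quadratic (three-point parabola) interpolation around
#' the best grid point. If the maximum lies on the window edge there is no
#' spurt peak and \code{found_peak} is \code{FALSE} (the "no peak"
#' case that arises for some percent-velocity curves); takeoff is then
#' undefined too. Ties between equal maxima resolve to the earliest age.
#'
#' @param curve a [curve_grid()] of velocities (cm/yr or \%/yr).
#' @param window optional age pair restricting the search.
#' @return An object of class \code{"landmarks"}: list with
#'   \code{age_takeoff}, \code{age_peak}, \code{vel_takeoff},
#'   \code{vel_peak}, \code{found_peak}, \code{found_takeoff} and the
#'   velocity \code{scale}.
#' @export
find_landmarks <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "curve_grid"))
  age <- curve$age
  val <- curve$value
  if (!is.null(window)) {
    keep <- age >= window[1] & age <= window[2]
    if (!any(keep)) stop("empty search window")
    age <- age[keep]; val <- val[keep]
  }
  n <- length(age)
  out <- structure(list(age_takeoff = NA_real_, age_peak = NA_real_,
                        vel_takeoff = NA_real_, vel_peak = NA_real_,
                        found_peak = FALSE, found_takeoff = FALSE,
                        scale = attr(curve, "scale")),
                   class = "landmarks")
  if (n < 3L) return(out)
  ipk <- which.max(val)                 # earliest age on exact ties
  if (ipk == 1L || ipk == n) return(out)
  pk <- .parabola_refine(age, val, ipk)
  out$age_peak <- pk[1]; out$vel_peak <- pk[2]; out$found_peak <- TRUE
  ito <- which.min(val[1:(ipk - 1L)])
  if (ito > 1L) {
    to <- .parabola_refine(age, val, ito)
    out$age_takeoff <- to[1]; out$vel_takeoff <- to[2]
    out$found_takeoff <- TRUE
  }
  out
}

#' @export
print.landmarks <- function(x, ...) {
  if (!x$found_peak) {
    cat("no peak on", x$scale, "velocity curve\n")
    return(invisible(x))
  }
  cat("peak:   ", format(x$vel_peak, digits = 3), x$scale, "at",
      format(x$age_peak, digits = 4), "yr\n")
  if (x$found_takeoff)
    cat("takeoff:", format(x$vel_takeoff, digits = 3), x$scale, "at",
        format(x$age_takeoff, digits = 4), "yr\n")
  else cat("takeoff: not found before peak\n")
  invisible(x)
}

#' Landmark summary of a fitted model
#'
#' Computes takeoff/peak ages and velocities on both the cm/yr and \%/yr
#' scales, plus the mean-curve value at age 19 — one row in the layout of
#' the per-model landmark summary table.
#'
#' @param fit a [fit_sitar()] object.
#' @param grid optional age grid.
#' @return A one-row data frame.
#' @export
landmark_summary <- function(fit, grid = .default_grid(fit)) {
  lv <- find_landmarks(velocity_curve(fit, grid = grid))
  lp <- find_landmarks(percent_velocity_curve(fit, grid = grid))
  data.frame(
    age_takeoff = lv$age_takeoff, age_peak = lv$age_peak,
    takeoff_cm_yr = lv$vel_takeoff, peak_cm_yr = lv$vel_peak,
    takeoff_pct_yr = if (lp$found_takeoff) lp$vel_takeoff else NA_real_,
    peak_pct_yr = if (lp$found_peak) lp$vel_peak else NA_real_,
    value_at_19 = value_at_age(fit, 19))
}

#' Compare two curves on a shared grid
#'
#' @param local,predicted [curve_grid()] objects on identical age grids.
#' @return List with \code{max_abs_diff} and \code{rmse} (same units as
#'   the curves) plus the pointwise difference.
#' @export
compare_curves <- function(local, predicted) {
  stopifnot(inherits(local, "curve_grid"), inherits(predicted, "curve_grid"))
  if (length(local$age) != length(predicted$age) ||
      any(abs(local$age - predicted$age) > 1e-8))
    stop("curves are not on the same age grid")
  d <- local$value - predicted$value
  list(max_abs_diff = max(abs(d)), rmse = sqrt(mean(d^2)),
       age = local$age, diff = d)
}
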