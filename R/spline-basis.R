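#' Natural cubic spline specification
#'
#' Defines a natural cubic spline basis by its degrees of freedom and knot
#' positions on the working age axis (log-transformed and centred when the
#' model uses log age). The basis has \code{df} columns, excludes the
#' intercept, is twice continuously differentiable, and has zero second
#' derivative at and beyond the boundary knots, so extrapolation beyond the
#' boundaries is linear.
#'
#' @param df integer number of basis columns (excluding the intercept),
#'   at least 2.
#' @param interior_knots numeric vector of \code{df - 1} strictly increasing
#'   values strictly inside the boundary knots.
#' @param boundary_knots numeric length-2 vector, the boundary knot pair.
#' @param use_log_age logical; whether the axis these knots live on is
#'   centred log age (\code{TRUE}) or centred age in years.
#' @return An object of class \code{"spline_spec"}.
#' @seealso [place_knots()], [build_basis()], [basis_derivative()]
#' @export
spline_spec <- function(df, interior_knots, boundary_knots, use_log_age = TRUE) {
  df <- as.integer(df)
  if (df < 2L)
    stop("df must be at least 2")
  if (length(interior_knots) != df - 1L)
    stop("need exactly df - 1 = ", df - 1L, " interior knots, got ",
         length(interior_knots))
  if (length(boundary_knots) != 2L || diff(boundary_knots) <= 0)
    stop("boundary_knots must be an increasing pair")
  if (is.unsorted(interior_knots, strictly = TRUE))
    stop("interior knots must be strictly increasing")
  if (any(interior_knots <= boundary_knots[1]) ||
      any(interior_knots >= boundary_knots[2]))
    stop("interior knots must lie strictly inside the boundary knots")
  structure(
    list(df = df,
         interior_knots = as.numeric(interior_knots),
         boundary_knots = as.numeric(boundary_knots),
         use_log_age = isTRUE(use_log_age)),
    class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat("Natural cubic spline: df =", x$df,
      if (x$use_log_age) "(log-age axis)" else "(age axis)", "\n")
  cat("  boundary knots:", format(x$boundary_knots, digits = 4), "\n")
  cat("  interior knots:", format(x$interior_knots, digits = 4), "\n")
  invisible(x)
}

#' Place spline knots at equally spaced quantiles
#'
#' Interior knots go at the k/df quantiles (k = 1, ..., df - 1) of the
#' supplied axis values, boundary knots at their range. This is the
#' data-driven placement used throughout the package: knots follow the
#' density of observation ages.
#'
#' @param x_sample numeric axis values (e.g. centred log ages of all
#'   observations).
#' @param df integer degrees of freedom (basis columns, excluding
#'   intercept).
#' @inheritParams spline_spec
#' @return A [spline_spec()] object.
#' @export
place_knots <- function(x_sample, df, use_log_age = TRUE) {
  df <- as.integer(df)
  x_sample <- x_sample[is.finite(x_sample)]
  ndist <- length(unique(x_sample))
  if (ndist < df + 1L)
    stop("need at least df + 1 = ", df + 1L,
         " distinct axis values to place knots, got ", ndist)
  probs <- seq_len(df - 1L) / df
  ik <- unname(stats::quantile(x_sample, probs, type = 7))
  bk <- range(x_sample)
  ## quantile ties (heavily duplicated x) would violate strict ordering
  if (anyDuplicated(ik) || any(ik <= bk[1]) || any(ik >= bk[2])) {
    ik <- unname(stats::quantile(unique(x_sample), probs, type = 7))
  }
  spline_spec(df, ik, bk, use_log_age)
}

## Full knot sequence and the QR factor enforcing the natural (zero second
## derivative at the boundaries) constraint. B-spline order 4 throughout.
.ns_constraint <- function(spec) {
  Ak <- sort(c(rep(spec$boundary_knots, 4L), spec$interior_knots))
  C2 <- splines::splineDesign(Ak, spec$boundary_knots, ord = 4L,
                              derivs = c(2L, 2L))
  list(Aknots = Ak, qrc = qr(t(C2)))
}

.ns_project <- function(con, B) {
  ## drop the two constrained directions, then the leading column, whose
  ## role is taken by the model's explicit intercept
  N <- t(qr.qty(con$qrc, t(B)))[, -(1:2), drop = FALSE]
  N[, -1, drop = FALSE]
}

.ns_eval <- function(spec, x, deriv = 0L, con = .ns_constraint(spec)) {
  bk <- spec$boundary_knots
  xx <- pmin(pmax(x, bk[1]), bk[2])
  B <- splines::splineDesign(con$Aknots, xx, ord = 4L,
                             derivs = rep(deriv, length(xx)))
  N <- .ns_project(con, B)
  lo <- x < bk[1]
  hi <- x > bk[2]
  if (any(lo) || any(hi)) {
    for (side in 1:2) {
      sel <- if (side == 1L) lo else hi
      if (!any(sel)) next
      N0 <- .ns_project(con, splines::splineDesign(con$Aknots, bk[side], 4L,
                                                   derivs = 0L))
      N1 <- .ns_project(con, splines::splineDesign(con$Aknots, bk[side], 4L,
                                                   derivs = 1L))
      if (deriv == 0L) {
        N[sel, ] <- rep(1, sum(sel)) %o% drop(N0) +
          (x[sel] - bk[side]) %o% drop(N1)
      } else if (deriv == 1L) {
        N[sel, ] <- rep(1, sum(sel)) %o% drop(N1)
      } else {
        N[sel, ] <- 0
      }
    }
  }
  dimnames(N) <- NULL
  N
}

#' Evaluate the natural cubic spline basis
#'
#' Returns the basis matrix (one column per degree of freedom, no intercept
#' column) at the given axis values. Beyond the boundary knots the basis
#' continues linearly, as implied by the natural conditions; no warning is
#' issued because subject-specific age shifts routinely push evaluation
#' slightly outside the data range.
#'
#' @param x numeric axis values.
#' @param spec a [spline_spec()] object.
#' @return numeric matrix, \code{length(x)} by \code{spec$df}.
#' @export
build_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  .ns_eval(spec, x, 0L)
}

#' Analytic first derivative of the spline basis
#'
#' Entrywise derivative of [build_basis()] with respect to the axis
#' variable; exact polynomial arithmetic, constant beyond the boundary
#' knots.
#'
#' @inheritParams build_basis
#' @return numeric matrix, \code{length(x)} by \code{spec$df}.
#' @export
basis_derivative <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  .ns_eval(spec, x, 1L)
}

#' @export
as.list.spline_spec <- function(x, ...) {
  list(df = x$df, interior_knots = x$interior_knots,
       boundary_knots = x$boundary_knots, use_log_age = x$use_log_age)
}

#' Rebuild a spline specification from its plain-list form
#'
#' Inverse of \code{as.list()} on a \code{spline_spec}; used when reading
#' configuration files.
#'
#' @param x a list with entries \code{df}, \code{interior_knots},
#'   \code{boundary_knots}, \code{use_log_age}.
#' @return A [spline_spec()] object.
#' @export
spline_spec_from_list <- function(x) {
  spline_spec(x$df, x$interior_knots, x$boundary_knots,
              isTRUE(x$use_log_age))
}
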