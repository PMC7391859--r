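## Core SITAR model:  y_ij = alpha_i + h[(x_ij - b0 - beta_i) exp(c0 + gamma_i)] + e_ij
## with x the centred (log-) age axis, h a natural cubic spline, and
## (alpha, beta, gamma) ~ trivariate normal subject random effects.
## The axis is centred at the log of the median observation age so that the
## intensity scaling pivots at the centre of the data; pivoting at x = 0
## instead makes timing and intensity nearly collinear and destabilises the
## fit.

.EFFECTS <- c(size = "a", timing = "b", intensity = "c")

## model function factory: builds the nlme model function for a given
## spline spec, with analytic gradients for all fixed and random effects.
## The timing (b) and intensity (c) parameters are included only when the
## corresponding random effect is in the model: their fixed effects exist
## to give the random effects mean zero, and with the random effect
## omitted they are redundant with the spline (the timing gradient lies
## close to the spline's span, which makes the fit singular).
.make_model_fn <- function(spec, use_b = TRUE, use_c = TRUE) {
  con <- .ns_constraint(spec)
  df <- spec$df
  snames <- paste0("s", seq_len(df))
  pnames <- c("a", if (use_b) "b", if (use_c) "c", snames)
  fn <- function(x) NULL
  formals(fn) <- c(formals(fn),
                   stats::setNames(rep(list(quote(expr = )),
                                       length(pnames)), pnames))
  bexpr <- if (use_b) "b" else "0"
  cexpr <- if (use_c) "exp(c)" else "1"
  body(fn) <- parse(text = paste0(
    "{\n",
    "  s <- cbind(", paste(snames, collapse = ", "), ")\n",
    "  xs <- (x - ", bexpr, ") * ", cexpr, "\n",
    "  B <- .ns_eval(spec, xs, 0L, con)\n",
    "  B1 <- .ns_eval(spec, xs, 1L, con)\n",
    "  hp <- rowSums(B1 * s)\n",
    "  val <- a + rowSums(B * s)\n",
    "  grad <- cbind(1, ",
    if (use_b) paste0("-", cexpr, " * hp, ") else "",
    if (use_c) "xs * hp, " else "",
    "B)\n",
    "  colnames(grad) <- pnames\n",
    "  attr(val, 'gradient') <- grad\n",
    "  val\n",
    "}"))[[1]]
  environment(fn) <- list2env(
    list(spec = spec, con = con, pnames = pnames, .ns_eval = .ns_eval),
    parent = getNamespace("pubgrowth"))
  fn
}

#' Fit the SITAR growth curve model
#'
#' Fits a shape-invariant nonlinear mixed-effects model: a common natural
#' cubic spline mean curve, shifted vertically by a subject \emph{size}
#' effect, horizontally by a \emph{timing} effect and compressed or
#' stretched along the age axis by an \emph{intensity} effect. By default
#' age enters after natural log transformation, so timing shifts are
#' proportional age shifts and intensity is a dimensionless log rate.
#' Estimation uses first-order conditional linearization (Lindstrom-Bates,
#' via \pkg{nlme}) with analytic model gradients.
#'
#' @param data a [growth_data()] object.
#' @param df spline degrees of freedom (basis columns excluding the
#'   intercept); ignored when \code{spec} is given.
#' @param use_log_age logical; model on the log-age axis (default) or the
#'   year axis.
#' @param include_effects character subset of
#'   \code{c("size", "timing", "intensity")}: which subject random effects
#'   to include. Excluded effects are fixed at zero for every subject and
#'   carry no variance parameters. An empty subset gives the
#'   fixed-effects-only spline fit.
#' @param spec optional [spline_spec()] on the centred working axis;
#'   default places knots at equally spaced quantiles of the observed
#'   (transformed) ages.
#' @param re_structure \code{"full"} (unstructured random-effect
#'   covariance) or \code{"diagonal"}.
#' @param control an [nlme::nlmeControl()] list.
#' @param verbose logical, passed to \code{nlme}.
#' @return An object of class \code{"sitar_fit"}: a list with the spline
#'   \code{spec}, axis offset \code{xoffset}, fixed effects
#'   (\code{coefficients$intercept}, \code{coefficients$spline},
#'   \code{beta0}, \code{gamma0}), random-effect covariance \code{re_cov},
#'   per-subject BLUPs \code{blups}, residual SD \code{sigma_r},
#'   \code{loglik}, \code{n_params}, \code{bic}, \code{converged} flag,
#'   \code{median_age}, a \code{fit_log} of estimation events, and the
#'   data the model was fitted to.
#' @references The model, its random-effect structure and the log-age
#'   convention follow the SITAR formulation standard in pubertal growth
#'   analysis.
#' @export
fit_sitar <- function(data, df = 5L, use_log_age = TRUE,
                      include_effects = c("size", "timing", "intensity"),
                      spec = NULL, re_structure = c("full", "diagonal"),
                      control = NULL, verbose = FALSE) {
  data <- growth_data(data)
  re_structure <- match.arg(re_structure)
  if (is.null(include_effects) || length(include_effects) == 0L) {
    include_effects <- character(0)
  } else {
    include_effects <- match.arg(include_effects,
                                 c("size", "timing", "intensity"),
                                 several.ok = TRUE)
  }
  med_age <- stats::median(data$age)
  xoffset <- if (use_log_age) log(med_age) else med_age
  xraw <- if (use_log_age) log(data$age) else data$age
  x <- xraw - xoffset
  if (is.null(spec)) {
    spec <- place_knots(x, df, use_log_age = use_log_age)
  } else {
    stopifnot(inherits(spec, "spline_spec"))
    df <- spec$df
  }
  d <- data.frame(y = data$value, x = x, id = factor(data$id))
  snames <- paste0("s", seq_len(spec$df))

  ## starting values: OLS spline for the mean curve, zero shifts
  X <- build_basis(d$x, spec)
  ols <- stats::lm.fit(cbind(1, X), d$y)
  sigma_f <- sqrt(sum(ols$residuals^2) / max(1, length(d$y) - spec$df - 1L))
  start <- c(ols$coefficients[1], 0, 0, ols$coefficients[-1])
  names(start) <- c("a", "b", "c", snames)

  fit_log <- character(0)
  log_add <- function(msg) fit_log <<- c(fit_log, msg)

  if (length(include_effects) == 0L) {
    ## fixed-effects-only spline fit (b, c pinned at zero: without random
    ## effects the age shift and scale are absorbed by the spline)
    N <- nrow(d)
    p <- spec$df + 2L           # intercept + spline + sigma
    sigma_ml <- sqrt(sum(ols$residuals^2) / N)
    ll <- -N / 2 * (log(2 * pi * sigma_ml^2) + 1)
    log_add("fixed-effects-only spline fit (no random effects)")
    return(.new_sitar_fit(
      spec = spec, xoffset = xoffset, use_log_age = use_log_age,
      intercept = unname(start["a"]), spline = unname(start[snames]),
      beta0 = 0, gamma0 = 0,
      re_cov = matrix(0, 3, 3, dimnames = list(names(.EFFECTS), names(.EFFECTS))),
      blups = data.frame(id = levels(d$id), size = 0, timing = 0,
                         intensity = 0, stringsAsFactors = FALSE),
      sigma_r = sigma_f, loglik = ll, n_params = p, N = N,
      n = nlevels(d$id), converged = TRUE, median_age = med_age,
      include_effects = include_effects, fit_log = fit_log,
      sigma_f = sigma_f, data = data, engine = NULL))
  }

  fenv <- new.env(parent = getNamespace("pubgrowth"))
  ## nlme resolves the model function through an evaluation chain ending
  ## at the global environment, so the model function is bound there for
  ## the duration of the fit (dot-prefixed, restored on exit)
  fname <- ".pubgrowth_active_model"
  had_old <- exists(fname, envir = globalenv(), inherits = FALSE)
  old_fn <- if (had_old) get(fname, envir = globalenv()) else NULL
  on.exit({
    if (had_old) assign(fname, old_fn, envir = globalenv())
    else if (exists(fname, envir = globalenv(), inherits = FALSE))
      rm(list = fname, envir = globalenv())
  }, add = TRUE)
  if (is.null(control))
    control <- nlme::nlmeControl(maxIter = 50L, pnlsMaxIter = 10L,
                                 msMaxIter = 100L, tolerance = 1e-6,
                                 returnObject = TRUE)

  try_fit <- function(effects, structure) {
    use_b <- "timing" %in% effects
    use_c <- "intensity" %in% effects
    pnames <- c("a", if (use_b) "b", if (use_c) "c", snames)
    assign(fname, .make_model_fn(spec, use_b, use_c), envir = globalenv())
    mform <- stats::as.formula(
      paste("y ~", fname, "(x,", paste(pnames, collapse = ", "), ")"),
      env = fenv)
    fixf <- stats::as.formula(
      paste(paste(pnames, collapse = " + "), "~ 1"), env = fenv)
    rf <- stats::as.formula(
      paste(paste(unname(.EFFECTS[effects]), collapse = " + "), "~ 1"),
      env = fenv)
    rnd <- if (structure == "full") nlme::pdLogChol(rf) else nlme::pdDiag(rf)
    ## the call is evaluated inside fenv (the data/controls live there)
    assign(".d", d, envir = fenv)
    assign(".rnd", rnd, envir = fenv)
    assign(".start", start[pnames], envir = fenv)
    assign(".control", control, envir = fenv)
    cl <- bquote(nlme::nlme(.(mform), fixed = .(fixf), random = .rnd,
                            groups = ~id, data = .d, start = .start,
                            control = .control, method = "ML",
                            verbose = .(verbose)))
    conv <- TRUE
    res <- withCallingHandlers(
      tryCatch(eval(cl, fenv), error = function(e) e),
      warning = function(w) {
        if (grepl("maxIter|iteration", conditionMessage(w)))
          conv <<- FALSE
        invokeRestart("muffleWarning")
      })
    list(fit = res, converged = conv)
  }

  ## estimation attempts: full covariance, then diagonal, then dropping
  ## effects (intensity first) if the covariance is singular/unestimable
  plans <- list(list(effects = include_effects, structure = re_structure))
  if (re_structure == "full" && length(include_effects) > 1L)
    plans <- c(plans, list(list(effects = include_effects,
                                structure = "diagonal")))
  for (k in rev(seq_len(length(include_effects) - 1L)))
    plans <- c(plans, list(list(effects = include_effects[seq_len(k)],
                                structure = "full")))

  engine <- NULL; eff_used <- include_effects; conv <- FALSE
  for (p in plans) {
    r <- try_fit(p$effects, p$structure)
    if (!inherits(r$fit, "error")) {
      engine <- r$fit; eff_used <- p$effects; conv <- r$converged
      if (!identical(p$effects, include_effects) ||
          !identical(p$structure, re_structure))
        log_add(paste0("refitted with effects {",
                       paste(p$effects, collapse = ","), "}, ",
                       p$structure, " covariance"))
      if (!conv) log_add("maximum iterations reached without convergence")
      break
    }
    log_add(paste0("attempt {", paste(p$effects, collapse = ","), "}, ",
                   p$structure, " failed: ", conditionMessage(r$fit)))
  }
  if (is.null(engine))
    stop("SITAR fit failed in all attempted configurations:\n  ",
         paste(fit_log, collapse = "\n  "))

  fe <- nlme::fixef(engine)
  if (!("b" %in% names(fe))) fe["b"] <- 0
  if (!("c" %in% names(fe))) fe["c"] <- 0
  ## relative covariance of the pdMat times sigma^2 = RE covariance
  vc <- as.matrix(engine$modelStruct$reStruct$id) * engine$sigma^2
  re_cov <- matrix(0, 3, 3, dimnames = list(names(.EFFECTS), names(.EFFECTS)))
  idx <- match(rownames(vc), .EFFECTS)
  re_cov[idx, idx] <- as.matrix(vc)

  reb <- nlme::ranef(engine)
  blups <- data.frame(id = rownames(reb), size = 0, timing = 0,
                      intensity = 0, stringsAsFactors = FALSE)
  for (ef in eff_used)
    blups[[ef]] <- reb[[.EFFECTS[[ef]]]]

  ll <- stats::logLik(engine)
  .new_sitar_fit(
    spec = spec, xoffset = xoffset, use_log_age = use_log_age,
    intercept = unname(fe["a"]), spline = unname(fe[snames]),
    beta0 = unname(fe["b"]), gamma0 = unname(fe["c"]),
    re_cov = re_cov, blups = blups, sigma_r = engine$sigma,
    loglik = as.numeric(ll), n_params = attr(ll, "df"), N = nrow(d),
    n = nlevels(d$id), converged = conv, median_age = med_age,
    include_effects = eff_used, fit_log = fit_log,
    sigma_f = sigma_f, data = data, engine = engine)
}

.new_sitar_fit <- function(spec, xoffset, use_log_age, intercept, spline,
                           beta0, gamma0, re_cov, blups, sigma_r, loglik,
                           n_params, N, n, converged, median_age,
                           include_effects, fit_log, sigma_f, data, engine) {
  structure(list(
    spec = spec, xoffset = xoffset, use_log_age = use_log_age,
    coefficients = list(intercept = intercept, spline = spline),
    beta0 = beta0, gamma0 = gamma0, re_cov = re_cov, blups = blups,
    sigma_r = sigma_r, loglik = loglik, n_params = n_params, N = N, n = n,
    bic = -2 * loglik + n_params * log(N), converged = converged,
    median_age = median_age, include_effects = include_effects,
    fit_log = fit_log, sigma_f = sigma_f, data = data, engine = engine),
    class = "sitar_fit")
}

#' @export
print.sitar_fit <- function(x, ...) {
  cat("SITAR fit:", x$n, "subjects,", x$N, "records, df =", x$spec$df,
      if (x$use_log_age) "(log age)" else "(age)", "\n")
  cat("  random effects:",
      if (length(x$include_effects)) paste(x$include_effects, collapse = ", ")
      else "none", "\n")
  sds <- re_sds(x)
  cat("  RE SDs: size", format(sds["size"], digits = 3), "cm, timing",
      format(sds["timing"], digits = 3),
      if (x$use_log_age) "log-age" else "yr", "(",
      format(timing_sd_years(x), digits = 3), "yr ), intensity",
      format(sds["intensity"], digits = 3), "\n")
  cat("  residual SD:", format(x$sigma_r, digits = 3),
      " logLik:", format(x$loglik, digits = 8),
      " BIC:", format(x$bic, digits = 8), "\n")
  if (!x$converged) cat("  NOT CONVERGED\n")
  if (length(x$fit_log)) cat("  fit log:", paste(x$fit_log, collapse = "; "), "\n")
  invisible(x)
}

#' Random-effect standard deviations of a SITAR fit
#'
#' @param fit a [fit_sitar()] object.
#' @return Named numeric vector (size, timing, intensity); timing is on the
#'   working (log-age) axis. Zero for effects excluded from the model.
#' @export
re_sds <- function(fit) {
  stopifnot(inherits(fit, "sitar_fit"))
  sqrt(diag(fit$re_cov))
}

#' Random-effect correlation matrix of a SITAR fit
#'
#' Computed from the estimated covariance matrix (not from BLUP sample
#' correlations, which shrinkage distorts).
#'
#' @param fit a [fit_sitar()] object.
#' @return 3x3 correlation matrix with NA where an effect is excluded.
#' @export
re_correlations <- function(fit) {
  v <- fit$re_cov
  s <- sqrt(diag(v))
  out <- v / (s %o% s)
  out[!is.finite(out)] <- NA_real_
  for (i in 1:3) out[i, i] <- if (s[i] > 0) 1 else NA_real_
  out
}

#' Predict an individual or mean growth curve
#'
#' Evaluates \code{alpha + h[(x - b0 - beta) exp(c0 + gamma)]} against age
#' in years, where \code{(alpha, beta, gamma)} is the supplied
#' random-effect triple. \code{re = c(0, 0, 0)} gives the population mean
#' curve.
#'
#' @param object a [fit_sitar()] object.
#' @param age numeric vector of ages in years.
#' @param re numeric length-3 random-effect triple (size cm, timing on the
#'   working axis, intensity log rate), or a subject id present in the fit
#'   to use that subject's BLUPs.
#' @param ... unused.
#' @return Numeric vector of predicted values (cm).
#' @export
predict.sitar_fit <- function(object, age, re = c(0, 0, 0), ...) {
  if (is.character(re) && length(re) == 1L) {
    row <- object$blups[object$blups$id == re, ]
    if (nrow(row) != 1L) stop("subject '", re, "' not in fit")
    re <- c(row$size, row$timing, row$intensity)
  }
  stopifnot(length(re) == 3L, all(is.finite(re)))
  if (object$use_log_age && any(age <= 0)) stop("ages must be positive")
  x <- (if (object$use_log_age) log(age) else age) - object$xoffset
  u <- (x - object$beta0 - re[2]) * exp(object$gamma0 + re[3])
  drop(object$coefficients$intercept + re[1] +
         build_basis(u, object$spec) %*% object$coefficients$spline)
}

#' @export
fitted.sitar_fit <- function(object, ...) {
  data <- object$data
  pred <- numeric(nrow(data))
  bl <- object$blups
  for (i in seq_len(nrow(bl))) {
    sel <- data$id == bl$id[i]
    if (any(sel))
      pred[sel] <- predict(object, data$age[sel],
                           re = c(bl$size[i], bl$timing[i], bl$intensity[i]))
  }
  pred
}

#' @export
residuals.sitar_fit <- function(object, ...) {
  object$data$value - fitted(object)
}

#' @export
logLik.sitar_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$N,
            class = "logLik")
}

#' @export
BIC.sitar_fit <- function(object, ...) object$bic

#' Standardized residuals of a SITAR fit
#'
#' Per-record z-scores: (observed - prediction with the subject's BLUPs)
#' divided by the residual SD. Used by the outlier-cleaning rule, which
#' flags records with |z| above 4 (only about 0.006\% of Gaussian data are
#' this extreme).
#'
#' @param fit a [fit_sitar()] object.
#' @param data optional [growth_data()]; defaults to the data the model
#'   was fitted to.
#' @return Numeric vector of z-scores, one per record.
#' @export
standardized_residuals <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "sitar_fit"))
  if (identical(data, fit$data)) return(residuals(fit) / fit$sigma_r)
  data <- growth_data(data)
  bl <- fit$blups
  pred <- numeric(nrow(data))
  for (i in seq_len(nrow(data))) {
    j <- match(data$id[i], bl$id)
    re <- if (is.na(j)) c(0, 0, 0)
          else c(bl$size[j], bl$timing[j], bl$intensity[j])
    pred[i] <- predict(fit, data$age[i], re = re)
  }
  (data$value - pred) / fit$sigma_r
}

#' Percentage of variance explained by the SITAR random effects
#'
#' Returns \code{100 (1 - sigma_r^2 / sigma_f^2)}, where \code{sigma_f} is
#' the residual SD of the companion model fitted without random effects,
#' i.e. with just the cubic spline mean curve, on the same data.
#'
#' @param fit a [fit_sitar()] object.
#' @param data optional data for the companion fit; defaults to the fit's
#'   own data.
#' @return Percent of variance explained.
#' @export
variance_explained <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "sitar_fit"))
  sigma_f <- if (identical(data, fit$data) && !is.null(fit$sigma_f)) {
    fit$sigma_f
  } else {
    data <- growth_data(data)
    x <- (if (fit$use_log_age) log(data$age) else data$age) - fit$xoffset
    X <- build_basis(x, fit$spec)
    r <- stats::lm.fit(cbind(1, X), data$value)$residuals
    sqrt(sum(r^2) / max(1, length(r) - fit$spec$df - 1L))
  }
  if (sigma_f <= 0)
    stop("degenerate data: fixed-effects-only fit has zero residual SD")
  100 * (1 - fit$sigma_r^2 / sigma_f^2)
}

#' Timing random-effect SD in years
#'
#' Under log age the timing SD is a proportional age shift; multiplying by
#' the median observation age converts it to years. Without the log
#' transform it is already in years and is returned unchanged.
#'
#' @param fit a [fit_sitar()] object.
#' @return Timing SD in years.
#' @export
timing_sd_years <- function(fit) {
  stopifnot(inherits(fit, "sitar_fit"))
  s <- sqrt(fit$re_cov["timing", "timing"])
  if (fit$use_log_age) s * fit$median_age else s
}

#' Size random-effect SD as a percentage of size at age 19
#'
#' @param fit a [fit_sitar()] object.
#' @return 100 * SD(size) / mean-curve value at age 19.
#' @export
size_percent_sd <- function(fit) {
  stopifnot(inherits(fit, "sitar_fit"))
  100 * sqrt(fit$re_cov["size", "size"]) / value_at_age(fit, 19)
}
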