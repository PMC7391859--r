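#' Choose spline degrees of freedom by BIC
#'
#' Fits the model for each candidate d.f. and returns the one minimising
#' the Bayesian Information Criterion \code{-2 logLik + p log N}. Ties go
#' to the smaller d.f.; non-converged candidates are recorded and
#' excluded with a warning.
#'
#' @param data a [growth_data()] object.
#' @param df_range integer vector of candidate degrees of freedom.
#' @param use_log_age logical, as in [fit_sitar()].
#' @param ... further arguments to [fit_sitar()].
#' @return List with \code{df} (the chosen value), \code{table} (data
#'   frame of df, BIC, logLik, converged) and \code{fits} (the fitted
#'   models, named by df).
#' @export
select_df <- function(data, df_range, use_log_age = TRUE, ...) {
  df_range <- sort(unique(as.integer(df_range)))
  fits <- list(); rows <- list()
  for (df in df_range) {
    f <- tryCatch(fit_sitar(data, df = df, use_log_age = use_log_age, ...),
                  error = function(e) e)
    if (inherits(f, "error")) {
      warning("df = ", df, " failed: ", conditionMessage(f))
      rows[[as.character(df)]] <- data.frame(df = df, bic = NA_real_,
                                             loglik = NA_real_,
                                             converged = FALSE)
      next
    }
    if (!f$converged)
      warning("df = ", df, " did not converge; excluded from selection")
    fits[[as.character(df)]] <- f
    rows[[as.character(df)]] <- data.frame(df = df, bic = f$bic,
                                           loglik = f$loglik,
                                           converged = f$converged)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- tab$converged & is.finite(tab$bic)
  if (!any(ok)) stop("no candidate df converged")
  best <- tab$df[ok][which.min(tab$bic[ok])]   # ties: first = smallest df
  list(df = best, table = tab, fits = fits)
}

#' Bootstrap standard errors for mean-curve landmarks
#'
#' Subject-level (cluster) bootstrap: subjects are resampled with
#' replacement — not records, which would break the within-subject
#' correlation of longitudinal data — the model is refitted, and the
#' mean-curve landmarks recomputed. SEs are the SDs across replicates.
#' Replicates whose velocity curve has no interior peak are excluded and
#' counted; more than 20\% such failures is an error (the model is too
#' unstable to bootstrap).
#'
#' @param data a [growth_data()] object.
#' @param df spline degrees of freedom for each refit.
#' @param B number of bootstrap replicates (at least 2).
#' @param seed integer seed; identical seeds give identical replicates.
#' @param use_log_age logical, as in [fit_sitar()].
#' @param statistic optional function of a fit returning a named numeric
#'   vector to bootstrap instead of the default velocity-curve landmarks
#'   (replicates where it returns any NA are excluded and counted).
#' @param ... further arguments to [fit_sitar()].
#' @return An object of class \code{"bootstrap_result"}: list with
#'   \code{B}, \code{replicates} (data frame of per-replicate landmark
#'   values), \code{se} (named vector of SDs), \code{n_failed} and
#'   \code{seed}.
#' @export
bootstrap_landmarks <- function(data, df, B = 200L, seed = 1L,
                                use_log_age = TRUE, statistic = NULL, ...) {
  data <- growth_data(data)
  if (B < 2L) stop("B must be at least 2")
  if (is.null(statistic))
    statistic <- function(fit) {
      lm <- find_landmarks(velocity_curve(fit))
      if (!lm$found_peak)
        return(c(apv = NA_real_, pv = NA_real_, age_takeoff = NA_real_,
                 vel_takeoff = NA_real_, value_at_19 = NA_real_))
      c(apv = lm$age_peak, pv = lm$vel_peak,
        age_takeoff = lm$age_takeoff, vel_takeoff = lm$vel_takeoff,
        value_at_19 = value_at_age(fit, 19))
    }
  ids <- unique(data$id)
  by_id <- split(as.data.frame(data), data$id)
  set.seed(seed)
  draws <- matrix(sample(length(ids), length(ids) * B, replace = TRUE),
                  nrow = B)
  rows <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    take <- draws[b, ]
    dd <- do.call(rbind, lapply(seq_along(take), function(k) {
      d <- by_id[[take[k]]]
      d$id <- sprintf("R%05d", k)      # duplicated subjects become distinct
      d
    }))
    rep_fit <- tryCatch(
      fit_sitar(growth_data(dd), df = df, use_log_age = use_log_age, ...),
      error = function(e) NULL)
    if (is.null(rep_fit)) { n_failed <- n_failed + 1L; next }
    st <- statistic(rep_fit)
    if (anyNA(st)) { n_failed <- n_failed + 1L; next }
    rows[[b]] <- data.frame(replicate = b, t(st))
  }
  if (n_failed > 0.2 * B)
    stop("bootstrap unstable: ", n_failed, " of ", B, " replicates failed")
  reps <- do.call(rbind, rows)
  se <- vapply(reps[, -1, drop = FALSE], stats::sd, numeric(1))
  structure(list(B = B, replicates = reps, se = se,
                 n_failed = n_failed, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Subject bootstrap:", x$B, "replicates (", x$n_failed, "failed ),",
      "seed", x$seed, "\n")
  cat("  SE(APV) =", format(x$se["apv"], digits = 3), "yr,  SE(PV) =",
      format(x$se["pv"], digits = 3), "cm/yr\n")
  invisible(x)
}
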