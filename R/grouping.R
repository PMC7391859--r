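## Global-to-local stratification: rank subjects by a random-effect BLUP,
## cut into (near-)equal groups, refit each group locally with the
## conditioned-on effect(s) omitted, and compare local mean curves against
## curves predicted from the global model at the group-mean random effects.

#' Split subjects into equal-size groups by a random-effect BLUP
#'
#' Subjects are ranked by the named effect's BLUP and assigned to
#' contiguous rank blocks, ordered from smallest to largest. When n is not
#' divisible by k the leftover subjects enlarge the outermost groups
#' (alternating low/high end), so group sizes never differ by more than
#' one. Ties in the BLUP break by subject id, making the split
#' deterministic.
#'
#' @param fit a [fit_sitar()] object whose model includes \code{effect}.
#' @param effect \code{"timing"} or \code{"intensity"} (or \code{"size"}).
#' @param k number of groups (at most the number of subjects).
#' @return An object of class \code{"group_assignment"}: data frame
#'   \code{subjects} (id, blup, group), \code{k}, the \code{effect}, and
#'   \code{group_means} — the k group-mean (size, timing, intensity) BLUP
#'   triples.
#' @export
split_by_blup <- function(fit, effect = c("timing", "intensity", "size"),
                          k = 9L) {
  stopifnot(inherits(fit, "sitar_fit"))
  effect <- match.arg(effect)
  if (!(effect %in% fit$include_effects))
    stop("fit has no '", effect, "' random effect")
  bl <- fit$blups
  n <- nrow(bl)
  if (k > n) stop("k = ", k, " exceeds the ", n, " subjects")
  ord <- order(bl[[effect]], bl$id)
  base <- n %/% k
  rem <- n %% k
  sizes <- rep(base, k)
  if (rem > 0) {
    ## extras at the extremes, outside in: groups 1, k, 2, k-1, ...
    extremes <- as.vector(rbind(seq_len(k), k + 1L - seq_len(k)))
    extremes <- unique(extremes)[seq_len(rem)]
    sizes[extremes] <- sizes[extremes] + 1L
  }
  grp <- rep(seq_len(k), times = sizes)
  subjects <- data.frame(id = bl$id[ord], blup = bl[[effect]][ord],
                         group = grp, stringsAsFactors = FALSE)
  gm <- do.call(rbind, lapply(seq_len(k), function(g) {
    sel <- bl$id %in% subjects$id[subjects$group == g]
    data.frame(group = g, n = sum(sel),
               size = mean(bl$size[sel]),
               timing = mean(bl$timing[sel]),
               intensity = mean(bl$intensity[sel]))
  }))
  structure(list(subjects = subjects, k = k, effect = effect,
                 group_means = gm),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Split into", x$k, "equal-size groups by", x$effect, "BLUP\n")
  print(x$group_means, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Fit local SITAR models per group
#'
#' One model per group, with the conditioned-on random effects omitted:
#' after splitting by timing, the timing random effect is dropped (it is
#' already adjusted for); after the second-stage split by intensity, both
#' timing and intensity are dropped.
#'
#' @param data the [growth_data()] the global model was fitted to.
#' @param assignment a [split_by_blup()] assignment.
#' @param df local spline degrees of freedom (default 5).
#' @param omit_effects random effects to omit from the local models.
#' @param use_log_age logical, as in [fit_sitar()].
#' @param ... further arguments to [fit_sitar()].
#' @return List of [fit_sitar()] objects (NULL where a group failed, with
#'   a warning).
#' @export
fit_local_models <- function(data, assignment, df = 5L,
                             omit_effects = "timing", use_log_age = TRUE,
                             ...) {
  stopifnot(inherits(assignment, "group_assignment"))
  data <- growth_data(data)
  include <- setdiff(c("size", "timing", "intensity"), omit_effects)
  lapply(seq_len(assignment$k), function(g) {
    ids <- assignment$subjects$id[assignment$subjects$group == g]
    d <- as.data.frame(data)[data$id %in% ids, , drop = FALSE]
    f <- tryCatch(
      fit_sitar(growth_data(d), df = df, use_log_age = use_log_age,
                include_effects = include, ...),
      error = function(e) e)
    if (inherits(f, "error")) {
      warning("group ", g, " local fit failed: ", conditionMessage(f))
      return(NULL)
    }
    f
  })
}

#' Predict a group's mean curve from the global model
#'
#' Evaluates the global model at the group's mean (size, timing,
#' intensity) BLUP triple — the "global prediction" against which the
#' locally fitted group curve is compared.
#'
#' @param fit_global the global [fit_sitar()] object.
#' @param assignment a [split_by_blup()] assignment from that fit.
#' @param group group index.
#' @param grid age grid (years); default 200 points over 9-19 yr.
#' @param what \code{"distance"} (cm) or \code{"velocity"} (cm/yr).
#' @return A [curve_grid()].
#' @export
predict_group_from_global <- function(fit_global, assignment, group,
                                      grid = seq(9, 19, length.out = 200L),
                                      what = c("distance", "velocity")) {
  stopifnot(inherits(assignment, "group_assignment"))
  what <- match.arg(what)
  gm <- assignment$group_means
  re <- as.numeric(gm[gm$group == group, c("size", "timing", "intensity")])
  if (what == "distance") distance_curve(fit_global, re = re, grid = grid)
  else velocity_curve(fit_global, re = re, grid = grid)
}

#' Two-stage timing-by-intensity stratification pipeline
#'
#' The full global-to-local procedure: fit a global model; split subjects
#' into \code{k_timing} equal groups by timing BLUP; fit a local model per
#' timing group with the timing random effect omitted; within each timing
#' group split by the \emph{local} model's intensity BLUPs into
#' \code{k_intensity} subgroups; and fit second-stage local models with
#' timing and intensity both omitted.
#'
#' @param data a [growth_data()] object.
#' @param k_timing,k_intensity group counts for the two stages (9 and 5
#'   give a median group in each direction and similar cell sizes).
#' @param df_global,df_local spline degrees of freedom for the global and
#'   local fits.
#' @param use_log_age logical, as in [fit_sitar()].
#' @param stage2 logical; run the second (intensity) stage.
#' @param grid comparison age grid.
#' @param ... further arguments to [fit_sitar()].
#' @return List with the \code{global} fit, stage-1 \code{assignment},
#'   \code{local_fits}, per-group curve comparisons \code{comparison}
#'   (local vs globally predicted distance curves), and, when
#'   \code{stage2}, \code{stage2} — per timing group the intensity
#'   assignment and subgroup fits.
#' @export
grouping_pipeline <- function(data, k_timing = 9L, k_intensity = 5L,
                              df_global = 6L, df_local = 5L,
                              use_log_age = TRUE, stage2 = TRUE,
                              grid = seq(9, 19, length.out = 200L), ...) {
  data <- growth_data(data)
  global <- fit_sitar(data, df = df_global, use_log_age = use_log_age, ...)
  assignment <- split_by_blup(global, "timing", k_timing)
  local_fits <- fit_local_models(data, assignment, df = df_local,
                                 omit_effects = "timing",
                                 use_log_age = use_log_age, ...)
  comparison <- lapply(seq_len(k_timing), function(g) {
    lf <- local_fits[[g]]
    if (is.null(lf)) return(NULL)
    loc <- distance_curve(lf, grid = grid)
    glo <- predict_group_from_global(global, assignment, g, grid = grid)
    compare_curves(loc, glo)
  })
  out <- list(global = global, assignment = assignment,
              local_fits = local_fits, comparison = comparison)
  if (stage2) {
    out$stage2 <- lapply(seq_len(k_timing), function(g) {
      lf <- local_fits[[g]]
      if (is.null(lf)) return(NULL)
      ids <- assignment$subjects$id[assignment$subjects$group == g]
      d <- growth_data(as.data.frame(data)[data$id %in% ids, , drop = FALSE])
      asg2 <- tryCatch(split_by_blup(lf, "intensity", k_intensity),
                       error = function(e) {
                         warning("timing group ", g, ": ",
                                 conditionMessage(e))
                         NULL
                       })
      if (is.null(asg2)) return(NULL)
      fits2 <- fit_local_models(d, asg2, df = df_local,
                                omit_effects = c("timing", "intensity"),
                                use_log_age = use_log_age, ...)
      list(assignment = asg2, fits = fits2)
    })
  }
  out
}

#' Per-group landmark and summary table
#'
#' One row per group in the layout of the grouped-model summary tables:
#' subjects, points, variance explained, residual SD, remaining
#' random-effect SDs, and mean-curve landmarks.
#'
#' @param local_fits list of per-group fits from [fit_local_models()].
#' @return Data frame, one row per group.
#' @export
group_summary <- function(local_fits) {
  rows <- lapply(seq_along(local_fits), function(g) {
    f <- local_fits[[g]]
    if (is.null(f))
      return(data.frame(group = g, n = NA, points = NA))
    lm <- find_landmarks(velocity_curve(f))
    data.frame(group = g, n = f$n, points = f$N,
               variance_explained = variance_explained(f),
               residual_sd = f$sigma_r,
               size_sd = sqrt(f$re_cov["size", "size"]),
               intensity_sd = sqrt(f$re_cov["intensity", "intensity"]),
               age_takeoff = lm$age_takeoff, age_peak = lm$age_peak,
               takeoff = lm$vel_takeoff, peak = lm$vel_peak,
               value_at_19 = value_at_age(f, 19))
  })
  do.call(rbind, rows)
}
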