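## Report writers: flat fit reports, model/random-effect/landmark summary
## tables in the standard column layouts, curve CSVs, and a flat
## key/value analysis configuration.

#' One-row model summary (fit statistics)
#'
#' Columns: subjects, points, median measurement, d.f., log-age flag,
#' variance explained (\%), residual SD, and residual CV (\% — residual SD
#' over the median of all observed values).
#'
#' @param fit a [fit_sitar()] object.
#' @return A one-row data frame.
#' @export
fit_summary_row <- function(fit) {
  stopifnot(inherits(fit, "sitar_fit"))
  med_val <- stats::median(fit$data$value)
  data.frame(
    measure = attr(fit$data, "measure") %||% NA_character_,
    sex = attr(fit$data, "sex") %||% NA_character_,
    subjects = fit$n, points = fit$N, median = med_val, df = fit$spec$df,
    log_age = fit$use_log_age,
    variance_explained = variance_explained(fit),
    residual_sd = fit$sigma_r,
    residual_cv = 100 * fit$sigma_r / med_val)
}

#' One-row random-effect summary
#'
#' Columns: the size SD in cm and as \% of size at 19, timing SD in
#' years, intensity SD, and the three pairwise correlations (from the
#' estimated covariance matrix).
#'
#' @param fit a [fit_sitar()] object.
#' @return A one-row data frame.
#' @export
re_summary_row <- function(fit) {
  stopifnot(inherits(fit, "sitar_fit"))
  sds <- re_sds(fit)
  rc <- re_correlations(fit)
  data.frame(
    measure = attr(fit$data, "measure") %||% NA_character_,
    sex = attr(fit$data, "sex") %||% NA_character_,
    size_sd_cm = sds[["size"]],
    size_sd_pct = size_percent_sd(fit),
    timing_sd_yr = timing_sd_years(fit),
    intensity_sd = sds[["intensity"]],
    cor_size_timing = rc["size", "timing"],
    cor_timing_intensity = rc["timing", "intensity"],
    cor_intensity_size = rc["intensity", "size"])
}

#' Write model, random-effect and landmark summary tables
#'
#' Produces three CSVs (\code{models.csv}, \code{random_effects.csv},
#' \code{landmarks.csv}) with one row per fit. In the landmark table,
#' percent-scale columns are written as \code{"*"} when the percent
#' velocity curve has no interior peak.
#'
#' @param fits list of [fit_sitar()] objects.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_summary_tables <- function(fits, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  t1 <- do.call(rbind, lapply(fits, fit_summary_row))
  t2 <- do.call(rbind, lapply(fits, re_summary_row))
  t3 <- do.call(rbind, lapply(fits, function(f) {
    r <- landmark_summary(f)
    r$measure <- attr(f$data, "measure") %||% NA_character_
    r$sex <- attr(f$data, "sex") %||% NA_character_
    r
  }))
  ## the "no peak on % velocity curve" marker
  for (col in c("takeoff_pct_yr", "peak_pct_yr"))
    t3[[col]] <- ifelse(is.na(t3[[col]]), "*", format(t3[[col]]))
  paths <- file.path(dir, c("models.csv", "random_effects.csv",
                            "landmarks.csv"))
  utils::write.csv(t1, paths[1], row.names = FALSE)
  utils::write.csv(t2, paths[2], row.names = FALSE)
  utils::write.csv(t3, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Write a curve to CSV
#'
#' Two columns (age, value), with a header naming the units.
#'
#' @param curve a [curve_grid()].
#' @param path output path.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "curve_grid"))
  df <- data.frame(age_yr = curve$age, value = curve$value)
  names(df)[2] <- paste0("value_", gsub("[^a-z%]", "",
                                        tolower(attr(curve, "scale"))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Flat key/value fit report
#'
#' Serializes the headline numbers of a fit (sample sizes, d.f., variance
#' explained, residual SD and CV, random-effect SDs and correlations,
#' convergence) as \code{key = value} lines, mirroring the summary-table
#' columns.
#'
#' @param fit a [fit_sitar()] object.
#' @param path output path; \code{NULL} returns the lines invisibly.
#' @return Character vector of report lines (invisibly if written).
#' @export
write_fit_report <- function(fit, path = NULL) {
  row <- cbind(fit_summary_row(fit), re_summary_row(fit)[, -(1:2)])
  lines <- c(paste0("converged = ", fit$converged),
             paste0(names(row), " = ",
                    vapply(row, function(v) format(v, digits = 6),
                           character(1))),
             if (length(fit$fit_log)) paste0("fit_log = ",
                                             paste(fit$fit_log,
                                                   collapse = " | ")))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Analysis configuration
#'
#' Bundles the knobs of a full analysis run: age window, age transform,
#' spline d.f. (or range to select over), random effects, bootstrap and
#' cleaning settings, and grouping parameters. Serializable to a flat
#' key/value file.
#'
#' @param age_window open age interval (years).
#' @param use_log_age logical.
#' @param df spline d.f., or an integer range for BIC selection.
#' @param include_effects random effects in the model.
#' @param boot_B,boot_seed bootstrap replicates and seed.
#' @param clean_threshold,clean_max_iter outlier cleaning settings.
#' @param k_timing,k_intensity,df_local grouping-pipeline settings.
#' @return A list of class \code{"analysis_config"}.
#' @export
analysis_config <- function(age_window = c(7, 20), use_log_age = TRUE,
                            df = 5L,
                            include_effects = c("size", "timing",
                                                "intensity"),
                            boot_B = 200L, boot_seed = 1L,
                            clean_threshold = 4, clean_max_iter = 3L,
                            k_timing = 9L, k_intensity = 5L,
                            df_local = 5L) {
  stopifnot(age_window[1] < age_window[2], all(df >= 2))
  structure(list(age_window = age_window, use_log_age = use_log_age,
                 df = df, include_effects = include_effects,
                 boot_B = boot_B, boot_seed = boot_seed,
                 clean_threshold = clean_threshold,
                 clean_max_iter = clean_max_iter, k_timing = k_timing,
                 k_intensity = k_intensity, df_local = df_local),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param config an \code{analysis_config}.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- analysis_config()
  for (p in kv) {
    key <- trimws(p[1])
    val <- strsplit(trimws(p[2]), ",")[[1]]
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num
                  else if (all(val %in% c("TRUE", "FALSE"))) as.logical(val)
                  else val
  }
  out
}
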