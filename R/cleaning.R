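#' Iterative outlier cleaning by standardized residual
#'
#' Fits the model, flags records whose standardized residual exceeds the
#' threshold in absolute value (default 4 — only about 0.006\% of Gaussian
#' data are this extreme), drops them, and refits, stopping when nothing
#' is flagged or after \code{max_iter} passes. Subjects whose records are
#' all removed disappear from the data but are listed in the report;
#' subjects with at least one remaining record are retained.
#'
#' @param data a [growth_data()] object.
#' @param df spline degrees of freedom for the cleaning fits.
#' @param threshold |z| above which a record is flagged.
#' @param max_iter maximum number of fit-flag-drop passes.
#' @param use_log_age logical, as in [fit_sitar()].
#' @param ... further arguments to [fit_sitar()].
#' @return List with \code{data} (the cleaned [growth_data()]) and
#'   \code{report}, a \code{"cleaning_report"}: per-iteration flagged
#'   records (subject, age, value, z), iteration count, initial and final
#'   record counts, and ids of fully removed subjects.
#' @export
clean_outliers <- function(data, df, threshold = 4, max_iter = 3L,
                           use_log_age = TRUE, ...) {
  data <- growth_data(data)
  n0 <- nrow(data)
  flagged <- list()
  it <- 0L
  current <- data
  repeat {
    fit <- fit_sitar(current, df = df, use_log_age = use_log_age, ...)
    z <- standardized_residuals(fit)
    bad <- which(abs(z) > threshold)
    if (length(bad) == 0L) break
    if (length(bad) == nrow(current))
      stop("all records flagged as outliers; data are pathological")
    it <- it + 1L
    flagged[[it]] <- data.frame(iteration = it,
                                id = current$id[bad],
                                age = current$age[bad],
                                value = current$value[bad],
                                z = z[bad])
    current <- growth_data(as.data.frame(current)[-bad, , drop = FALSE],
                           sex = attr(current, "sex"),
                           measure = attr(current, "measure"))
    if (it >= max_iter) break
  }
  flagged_df <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(iteration = integer(0), id = character(0),
               age = numeric(0), value = numeric(0), z = numeric(0))
  removed_subjects <- setdiff(unique(data$id), unique(current$id))
  report <- structure(list(iterations = it, flagged = flagged_df,
                           n_initial = n0, n_final = nrow(current),
                           threshold = threshold,
                           removed_subjects = removed_subjects),
                      class = "cleaning_report")
  list(data = current, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Outlier cleaning: |z| >", x$threshold, "over", x$iterations,
      "pass(es)\n")
  cat("  records:", x$n_initial, "->", x$n_final, "(",
      nrow(x$flagged), "flagged )\n")
  if (length(x$removed_subjects))
    cat("  subjects fully removed:",
        paste(x$removed_subjects, collapse = ", "), "\n")
  invisible(x)
}

#' Context for manual review of flagged records
#'
#' Returns each flagged record together with its subject's neighbouring
#' records, supporting case-by-case correction decisions outside the
#' package (the cleaning operation itself only excludes).
#'
#' @param report a cleaning report from [clean_outliers()].
#' @param data the original [growth_data()].
#' @param k number of neighbouring records each side.
#' @return A data frame of flagged records and their context rows.
#' @export
review_context <- function(report, data, k = 2L) {
  fl <- report$flagged
  if (nrow(fl) == 0L) return(fl)
  out <- lapply(seq_len(nrow(fl)), function(i) {
    d <- as.data.frame(data[data$id == fl$id[i], ])
    d <- d[order(d$age), ]
    j <- which.min(abs(d$age - fl$age[i]))
    idx <- max(1L, j - k):min(nrow(d), j + k)
    cbind(flag = seq_len(nrow(fl))[i], d[idx, c("id", "age", "value")],
          is_flagged = idx == j)
  })
  do.call(rbind, out)
}
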