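#' Longitudinal growth data
#'
#' A light wrapper around a long-format data frame of repeated
#' anthropometric measurements: one row per measurement occasion, with a
#' subject identifier, decimal age in years and the measured value in cm.
#' Optional \code{sex} and \code{measure} columns carry the stratum the
#' records belong to; every model in this package is fitted per sex and
#' per measurement.
#'
#' @param df data frame with columns \code{id}, \code{age}, \code{value}
#'   (and optionally \code{sex}, \code{measure}).
#' @param sex optional label recorded as an attribute.
#' @param measure optional measurement name recorded as an attribute.
#' @param units measurement units, default \code{"cm"}.
#' @return The data frame with class \code{"growth_data"} prepended and
#'   metadata attributes set.
#' @export
growth_data <- function(df, sex = NULL, measure = NULL, units = "cm") {
  df <- as.data.frame(df)
  need <- c("id", "age", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    stop("no records")
  if (!is.numeric(df$age) || !is.numeric(df$value))
    stop("age and value must be numeric")
  if (any(!is.finite(df$age)) || any(!is.finite(df$value)))
    stop("non-finite age or value")
  if (any(df$age <= 0))
    stop("ages must be positive (log age must be definable)")
  if (any(df$value <= 0))
    stop("values must be positive")
  df$id <- as.character(df$id)
  structure(df,
            sex = sex %||% attr(df, "sex"),
            measure = measure %||% attr(df, "measure"),
            units = units,
            class = unique(c("growth_data", class(df))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.growth_data <- function(x, ...) {
  cat("Growth data:", length(unique(x$id)), "subjects,", nrow(x),
      "records, ages", format(min(x$age), digits = 3), "to",
      format(max(x$age), digits = 3), "yr\n")
  if (!is.null(attr(x, "measure")))
    cat("  measure:", attr(x, "measure"),
        if (!is.null(attr(x, "sex"))) paste0("(", attr(x, "sex"), ")"), "\n")
  invisible(x)
}

#' Number of subjects / records in growth data
#' @param data a [growth_data()] object.
#' @return integer count.
#' @export
n_subjects <- function(data) length(unique(data$id))

#' @rdname n_subjects
#' @export
n_records <- function(data) nrow(data)

#' Read long-format growth data from CSV
#'
#' Expects columns \code{id}, \code{sex}, \code{age}, \code{measure},
#' \code{value}. Rows outside the configured age window are dropped with
#' strict inequalities (the default window keeps ages strictly greater
#' than 7 and strictly less than 20 years, focussing on puberty); the
#' number dropped is reported via \code{message()}.
#'
#' @param path CSV file path.
#' @param age_window numeric pair; open interval of ages retained.
#' @return A [growth_data()] object (all sexes/measures; use
#'   [split_strata()] to separate).
#' @export
read_growth_csv <- function(path, age_window = c(7, 20)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age", "measure", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  for (col in c("age", "value")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vnum <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vnum) & !is.na(v))
      if (length(bad))
        stop("non-numeric ", col, " at row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "))
      df[[col]] <- vnum
    }
  }
  keep <- df$age > age_window[1] & df$age < age_window[2]
  if (any(!keep))
    message(sum(!keep), " row(s) outside age window (",
            age_window[1], ", ", age_window[2], ") dropped")
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no records left after applying the age window")
  growth_data(df)
}

#' Write growth data to CSV
#'
#' Round-trips with [read_growth_csv()] (up to the age-window filter).
#'
#' @param data a [growth_data()] object.
#' @param path output CSV path.
#' @export
write_growth_csv <- function(data, path) {
  df <- as.data.frame(data)
  if (is.null(df$sex)) df$sex <- attr(data, "sex") %||% NA
  if (is.null(df$measure)) df$measure <- attr(data, "measure") %||% NA
  utils::write.csv(df[, c("id", "sex", "age", "measure", "value")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Split growth data into per-sex, per-measure strata
#'
#' @param data a [growth_data()] object with \code{sex} and/or
#'   \code{measure} columns.
#' @return Named list of [growth_data()] objects, one per stratum.
#' @export
split_strata <- function(data) {
  sex <- data$sex %||% rep("all", nrow(data))
  measure <- data$measure %||% rep("value", nrow(data))
  key <- paste(measure, sex, sep = ".")
  lapply(split(as.data.frame(data), key), function(d)
    growth_data(d, sex = as.character(d$sex[1] %||% NA),
                measure = as.character(d$measure[1] %||% NA)))
}
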