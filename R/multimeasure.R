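#' Cross-measurement correlations of a random effect
#'
#' Given per-measurement fits on (partly) shared subjects, computes the
#' Pearson correlation of one random effect's BLUPs between every pair of
#' measurements, over the subjects present in both fits. Pairs sharing
#' fewer than 3 subjects are marked missing.
#'
#' @param fits named list of [fit_sitar()] objects, one per measurement.
#' @param effect \code{"size"}, \code{"timing"} or \code{"intensity"}.
#' @return An object of class \code{"effect_cor_matrix"}: the correlation
#'   matrix with measurement names, with attributes \code{n} (pairwise
#'   subject counts), \code{effect} and \code{median_off_diagonal}.
#' @export
cross_measure_correlations <- function(fits, effect = c("size", "timing",
                                                        "intensity")) {
  effect <- match.arg(effect)
  stopifnot(length(fits) >= 2L, !is.null(names(fits)))
  m <- length(fits)
  nm <- names(fits)
  mat <- diag(1, m); dimnames(mat) <- list(nm, nm)
  nmat <- matrix(0L, m, m, dimnames = list(nm, nm))
  for (i in seq_len(m)) nmat[i, i] <- nrow(fits[[i]]$blups)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    bi <- fits[[i]]$blups; bj <- fits[[j]]$blups
    shared <- intersect(bi$id, bj$id)
    nmat[i, j] <- nmat[j, i] <- length(shared)
    if (length(shared) < 3L) {
      mat[i, j] <- mat[j, i] <- NA_real_
      next
    }
    r <- stats::cor(bi[[effect]][match(shared, bi$id)],
                    bj[[effect]][match(shared, bj$id)])
    mat[i, j] <- mat[j, i] <- r
  }
  off <- mat[upper.tri(mat)]
  structure(mat, n = nmat, effect = effect,
            median_off_diagonal = stats::median(off, na.rm = TRUE),
            class = c("effect_cor_matrix", "matrix"))
}

#' @export
print.effect_cor_matrix <- function(x, ...) {
  cat("Cross-measurement", attr(x, "effect"), "correlations (median",
      format(attr(x, "median_off_diagonal"), digits = 2), ")\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Seriate a correlation matrix
#'
#' Reorders the measurements so the most strongly associated migrate
#' towards the start (and large correlations towards the diagonal), by
#' ranking each measurement by its median correlation with the others —
#' descending, ties broken by name. The output matrix is a pure
#' permutation of the input: the multiset of entries is unchanged.
#'
#' @param mat an [cross_measure_correlations()] matrix (no missing
#'   entries).
#' @return List with \code{order} (measurement names, ranked) and
#'   \code{matrix} (the reordered correlation matrix).
#' @export
seriate_measures <- function(mat) {
  m <- unclass(mat)
  if (any(is.na(m)))
    stop("correlation matrix has missing entries; cannot seriate")
  med <- vapply(seq_len(nrow(m)), function(i)
    stats::median(m[i, -i]), numeric(1))
  ord <- order(-med, rownames(m))
  reord <- m[ord, ord]
  list(order = rownames(m)[ord], matrix = reord,
       median_correlation = stats::setNames(med[ord], rownames(m)[ord]))
}
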