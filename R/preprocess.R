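#' Filter features by chromatographic retention time
#'
#' Drops features eluting before `low` or after `high` seconds; features
#' exactly on a boundary are kept (the exclusion is strict: rt < low or
#' rt > high). Column order of the retained features is preserved.
#'
#' @param table a [feature_table()].
#' @param low,high retention-time window in seconds (defaults 90 and 660).
#' @return a `feature_table` with only the retained features. An empty
#'   result is an error (nothing left to model), preceded by a message
#'   with the counts.
#' @examples
#' \dontrun{filter_retention_time(ft, 90, 660)}
#' @export
filter_retention_time <- function(table, low = 90, high = 660) {
  stopifnot(inherits(table, "feature_table"))
  keep <- table$feature_rt >= low & table$feature_rt <= high
  message(sprintf("retention-time filter [%g, %g] s: kept %d of %d features",
                  low, high, sum(keep), length(keep)))
  if (!any(keep)) stopf("no features remain after retention-time filtering")
  ft_subset(table, features = keep)
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution by dividing each case's intensities by the
#' median quotient against a reference spectrum. The reference is the
#' per-feature median across the given case set; features with a zero
#' reference intensity are excluded from the quotient computation.
#'
#' @param table a [feature_table()] with at least 2 cases.
#' @param reference optional reference spectrum (per-feature numeric, as
#'   from a previous training-set normalization) to reuse instead of
#'   recomputing; this avoids information leaking from new cases into the
#'   reference.
#' @return A list of class `pqn_result` with
#'   `normalized` (a `feature_table`; input / factor),
#'   `dilution_factor` (per-case median quotient) and
#'   `reference_spectrum` (per-feature).
#' @details Multiplying one case's row by a constant c > 0 multiplies its
#'   dilution factor by c and leaves its normalized row unchanged.
#' @export
pqn_normalize <- function(table, reference = NULL) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities
  if (is.null(reference) && nrow(x) < 2L) {
    stopf("PQN needs at least 2 cases to compute a reference spectrum")
  }
  reference <- reference %||% apply(x, 2, stats::median)
  if (length(reference) != ncol(x)) {
    stopf("reference spectrum length (%d) != number of features (%d)",
          length(reference), ncol(x))
  }
  usable <- reference > 0
  if (!any(usable)) stopf("reference spectrum has no positive entries")
  factors <- apply(x[, usable, drop = FALSE], 1, function(row) {
    stats::median(row / reference[usable])
  })
  bad <- which(!is.finite(factors) | factors <= 0)
  if (length(bad)) {
    stopf("case(s) with no positive overlap with the reference spectrum: %s",
          paste(table$case_ids[bad], collapse = ", "))
  }
  normalized <- feature_table(x / factors, table$feature_mz, table$feature_rt,
                              case_ids = table$case_ids,
                              feature_ids = table$feature_ids)
  structure(list(normalized = normalized,
                 dilution_factor = stats::setNames(factors, table$case_ids),
                 reference_spectrum = stats::setNames(reference, table$feature_ids)),
            class = "pqn_result")
}

#' Log-transform and unit-variance scale a feature table
#'
#' Applies `log10(x + pseudo)` followed by per-feature centering and
#' scaling to unit sample standard deviation, the transform used for all
#' latent-variable modeling. The pseudo-value handles zero intensities:
#' when the table contains zeros, half the smallest positive intensity is
#' added to every value before the log; otherwise no pseudo-value is
#' needed. Zero-variance features cannot be scaled and are dropped with a
#' warning.
#'
#' @param table a [feature_table()].
#' @return A list of class `uv_transform` with `matrix` (cases x retained
#'   features, each column mean 0 / sd 1), `centers`, `scales`, `pseudo`
#'   (the pseudo-value used, possibly 0), `feature_ids` (retained) and
#'   `dropped` (zero-variance feature ids).
#' @seealso [apply_uv_transform()] for projecting new cases with stored
#'   parameters.
#' @export
log_uv_transform <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities
  pseudo <- 0
  if (any(x == 0)) {
    pos <- x[x > 0]
    if (!length(pos)) stopf("feature table is all zeros")
    pseudo <- min(pos) / 2
  }
  lx <- log10(x + pseudo)
  centers <- colMeans(lx)
  scales <- apply(lx, 2, stats::sd)
  drop <- !is.finite(scales) | scales == 0
  if (any(drop)) {
    warnf("dropping %d zero-variance feature(s): %s", sum(drop),
          paste(utils::head(table$feature_ids[drop], 5), collapse = ", "))
  }
  keep <- !drop
  m <- scale(lx[, keep, drop = FALSE], center = centers[keep], scale = scales[keep])
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  structure(list(matrix = m,
                 centers = centers[keep], scales = scales[keep],
                 pseudo = pseudo,
                 feature_ids = table$feature_ids[keep],
                 dropped = table$feature_ids[drop]),
            class = "uv_transform")
}

#' Project new cases with stored log/UV parameters
#'
#' @param transform a [log_uv_transform()] result (or any list carrying
#'   `centers`, `scales`, `pseudo`, `feature_ids`).
#' @param table a [feature_table()] containing at least the transform's
#'   features.
#' @return matrix of transformed values, columns in the transform's
#'   feature order.
#' @export
apply_uv_transform <- function(transform, table) {
  stopifnot(inherits(table, "feature_table"))
  pos <- match(transform$feature_ids, table$feature_ids)
  if (anyNA(pos)) {
    stopf("feature-set mismatch: %d transform feature(s) missing from table, e.g. %s",
          sum(is.na(pos)),
          paste(utils::head(transform$feature_ids[is.na(pos)], 5), collapse = ", "))
  }
  lx <- log10(table$intensities[, pos, drop = FALSE] + transform$pseudo)
  m <- scale(lx, center = transform$centers, scale = transform$scales)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  colnames(m) <- transform$feature_ids
  m
}

#' Coefficient of variation of quality-control peak areas
#'
#' Summarizes internal-standard stability across analytical runs as the
#' percent coefficient of variation, 100 * sd / mean (sample sd, n - 1).
#'
#' @param peak_areas numeric vector of at least 2 positive peak areas.
#' @return CV as a percentage.
#' @examples
#' qc_cv(c(10, 20))  # 47.14%
#' @export
qc_cv <- function(peak_areas) {
  if (length(peak_areas) < 2L) stopf("need at least 2 peak areas")
  m <- mean(peak_areas)
  if (!is.finite(m) || m <= 0) stopf("mean peak area must be positive")
  100 * stats::sd(peak_areas) / m
}
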