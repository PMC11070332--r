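#' Construct a sample-by-feature intensity table
#'
#' The central data container of the package: a non-negative intensity
#' matrix (rows = autopsy cases, columns = chromatographic features), with
#' per-feature mass-to-charge ratio and retention time, and unique case and
#' feature identifiers.
#'
#' @param intensities numeric matrix, cases in rows, features in columns;
#'   all values must be finite and non-negative.
#' @param feature_mz numeric vector of m/z values, one per feature.
#' @param feature_rt numeric vector of retention times in seconds, one per
#'   feature; must be non-negative.
#' @param case_ids character vector of unique case identifiers; defaults to
#'   the matrix rownames.
#' @param feature_ids character vector of unique feature identifiers;
#'   defaults to the matrix colnames.
#' @return An object of class `feature_table`: a list with elements
#'   `intensities`, `feature_mz`, `feature_rt`, `case_ids`, `feature_ids`.
#' @examples
#' m <- matrix(abs(rnorm(12, 100, 10)), 3, 4)
#' ft <- feature_table(m, feature_mz = c(100.1, 120.2, 130.3, 140.4),
#'                     feature_rt = c(95, 200, 300, 400))
#' dim(ft)
#' @export
feature_table <- function(intensities, feature_mz, feature_rt,
                          case_ids = NULL, feature_ids = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stopf("`intensities` must be a numeric matrix (cases x features)")
  }
  n <- nrow(intensities)
  k <- ncol(intensities)
  if (n == 0L || k == 0L) stopf("empty feature table (%d cases x %d features)", n, k)
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stopf("intensities contain missing or non-finite values")
  }
  if (any(intensities < 0)) stopf("intensities must be non-negative")
  case_ids <- as.character(case_ids %||% rownames(intensities) %||% paste0("case_", seq_len(n)))
  feature_ids <- as.character(feature_ids %||% colnames(intensities) %||% paste0("F", seq_len(k)))
  if (length(case_ids) != n) stopf("length(case_ids) != nrow(intensities)")
  if (length(feature_ids) != k) stopf("length(feature_ids) != ncol(intensities)")
  if (anyDuplicated(case_ids)) stopf("duplicate case identifiers")
  if (anyDuplicated(feature_ids)) stopf("duplicate feature identifiers")
  feature_mz <- as.numeric(feature_mz)
  feature_rt <- as.numeric(feature_rt)
  if (length(feature_mz) != k || length(feature_rt) != k) {
    stopf("feature_mz and feature_rt must each have one value per feature")
  }
  if (any(!is.finite(feature_rt)) || any(feature_rt < 0)) {
    stopf("retention times must be finite and >= 0 seconds")
  }
  dimnames(intensities) <- list(case_ids, feature_ids)
  structure(
    list(intensities = intensities, feature_mz = feature_mz,
         feature_rt = feature_rt, case_ids = case_ids,
         feature_ids = feature_ids),
    class = "feature_table"
  )
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d cases x %d features\n",
              nrow(x$intensities), ncol(x$intensities)))
  cat(sprintf("  rt range: %.1f-%.1f s, m/z range: %.4f-%.4f\n",
              min(x$feature_rt), max(x$feature_rt),
              min(x$feature_mz), max(x$feature_mz)))
  invisible(x)
}

#' Subset a feature table by cases and/or features
#'
#' @param table a [feature_table()].
#' @param cases case identifiers or a logical/integer index over cases.
#' @param features feature identifiers or a logical/integer index over
#'   features.
#' @return A `feature_table` restricted to the requested rows/columns.
#' @export
ft_subset <- function(table, cases = NULL, features = NULL) {
  stopifnot(inherits(table, "feature_table"))
  ci <- resolve_index(cases, table$case_ids, "case")
  fi <- resolve_index(features, table$feature_ids, "feature")
  feature_table(table$intensities[ci, fi, drop = FALSE],
                table$feature_mz[fi], table$feature_rt[fi],
                case_ids = table$case_ids[ci],
                feature_ids = table$feature_ids[fi])
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) {
      stopf("unknown %s identifier(s): %s", what,
            paste(utils::head(idx[is.na(pos)], 5), collapse = ", "))
    }
    return(pos)
  }
  if (is.logical(idx)) {
    if (length(idx) != length(ids)) stopf("logical %s index of wrong length", what)
    return(which(idx))
  }
  pos <- as.integer(idx)
  if (any(pos < 1L | pos > length(ids))) stopf("%s index out of range", what)
  pos
}

#' Write / read a feature table as delimited text
#'
#' The on-disk layout follows the convention of exported LC-MS peak tables:
#' one row per feature with columns `feature_id`, `mz`, `rt`, followed by
#' one intensity column per case.
#'
#' @param table a [feature_table()].
#' @param path file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(feature_id = table$feature_ids,
                   mz = table$feature_mz, rt = table$feature_rt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  inten <- t(table$intensities)
  colnames(inten) <- table$case_ids
  df <- cbind(df, as.data.frame(inten, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, sep = ",") {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% colnames(df))) {
    stopf("malformed feature table '%s': missing column(s) %s", path,
          paste(setdiff(need, colnames(df)), collapse = ", "))
  }
  if (nrow(df) == 0L) stopf("empty feature table in '%s'", path)
  case_cols <- setdiff(colnames(df), need)
  if (length(case_cols) == 0L) stopf("feature table '%s' has no sample columns", path)
  num <- function(col, colname) {
    v <- suppressWarnings(as.numeric(df[[colname]]))
    bad <- which(is.na(v) & !is.na(df[[colname]]) & df[[colname]] != "NA")
    if (length(bad) || anyNA(v)) {
      row <- if (length(bad)) bad[1] else which(is.na(v))[1]
      stopf("non-numeric value '%s' in column '%s', row %d (feature '%s') of '%s'",
            df[[colname]][row], colname, row, df$feature_id[row], path)
    }
    v
  }
  inten <- vapply(case_cols, function(cc) num(df[[cc]], cc), numeric(nrow(df)))
  # vapply gives features x cases already when nrow(df) > 1; ensure matrix
  inten <- matrix(inten, nrow = nrow(df), ncol = length(case_cols))
  feature_table(t(inten), num(df$mz, "mz"), num(df$rt, "rt"),
                case_ids = case_cols, feature_ids = df$feature_id)
}
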