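#' Single-label class assignment by maximal predicted response
#'
#' The default screening mode: every case is assigned to the class with
#' the largest predicted response. Exact ties are broken deterministically
#' by class order (first declared class wins) and flagged.
#'
#' @param responses matrix (cases x classes) of predicted responses, with
#'   class names as column names.
#' @return factor of assigned classes with attribute `ties`: indices of
#'   cases whose maximum was tied.
#' @export
classify_argmax <- function(responses) {
  responses <- rbind(responses)
  if (any(!is.finite(responses))) stopf("responses must be finite")
  classes <- colnames(responses) %||% paste0("class_", seq_len(ncol(responses)))
  idx <- apply(responses, 1, which.max)
  n_max <- apply(responses, 1, function(r) sum(r == max(r)))
  ties <- which(n_max > 1L)
  if (length(ties)) {
    message(sprintf("%d case(s) with tied maximal responses; first class in order assigned",
                    length(ties)))
  }
  out <- factor(classes[idx], levels = classes)
  attr(out, "ties") <- ties
  out
}

#' Receiver-operating-characteristic curve
#'
#' One-vs-rest ROC from continuous scores: thresholds are the sorted
#' unique scores (cases with equal scores move together), TPR/FPR are
#' cumulative rates as the threshold decreases, endpoints (0,0) and (1,1)
#' are always present, and AUC is the trapezoid-rule area.
#'
#' @param scores numeric vector, larger = more class-like.
#' @param is_class logical vector: TRUE for cases of the class.
#' @return An object of class `roc_curve`: data.frame `points` with
#'   columns `threshold`, `tpr`, `fpr` (threshold `Inf` for the (0,0)
#'   endpoint), and `auc`.
#' @export
roc_curve <- function(scores, is_class) {
  is_class <- as.logical(is_class)
  if (length(scores) != length(is_class)) stopf("scores and labels differ in length")
  n_pos <- sum(is_class); n_neg <- sum(!is_class)
  if (n_pos == 0L || n_neg == 0L) {
    stopf("ROC needs both classes present (got %d positive, %d negative)", n_pos, n_neg)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(s) sum(is_class & scores == s), numeric(1)))
  fp <- cumsum(vapply(thr, function(s) sum(!is_class & scores == s), numeric(1)))
  points <- data.frame(threshold = c(Inf, thr),
                       tpr = c(0, tp / n_pos), fpr = c(0, fp / n_neg))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.3f (%d positive / %d negative, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Specificity-optimized threshold from the steepest ROC segment
#'
#' Selects, among consecutive ROC segments whose upper endpoint (the
#' higher-TPR end) lies in the predetermined region TPR > `tpr_min` and
#' FPR < `fpr_max`, the segment with the steepest slope dTPR/dFPR; a
#' vertical segment (dFPR = 0) has infinite slope and is preferred. Ties
#' are broken toward lower FPR, and remaining ties (several segments of
#' one vertical rise) toward higher TPR, so a contiguous rise is used in
#' full. The returned threshold is the score cutoff realizing the
#' segment's upper endpoint.
#'
#' @param roc a [roc_curve()].
#' @param tpr_min,fpr_max the selection region (defaults 0.3 and 0.1).
#' @return list with `threshold`, `tpr`, `fpr` at the selected operating
#'   point.
#' @export
steepest_threshold <- function(roc, tpr_min = 0.3, fpr_max = 0.1) {
  stopifnot(inherits(roc, "roc_curve"))
  p <- roc$points
  n <- nrow(p)
  upper <- 2:n   # segment i runs from point i-1 to point i
  ok <- p$tpr[upper] > tpr_min & p$fpr[upper] < fpr_max
  if (!any(ok)) {
    stopf("no ROC segment has its upper endpoint inside TPR > %g, FPR < %g; relax the region",
          tpr_min, fpr_max)
  }
  d_tpr <- diff(p$tpr); d_fpr <- diff(p$fpr)
  slope <- ifelse(d_fpr == 0, Inf, d_tpr / d_fpr)
  slope[!ok] <- -Inf
  best <- which(slope == max(slope))
  if (length(best) > 1L) best <- best[p$fpr[best + 1L] == min(p$fpr[best + 1L])]
  if (length(best) > 1L) best <- best[which.max(p$tpr[best + 1L])]
  sel <- best + 1L
  list(threshold = p$threshold[sel], tpr = p$tpr[sel], fpr = p$fpr[sel])
}

#' Equal-error-rate threshold from a ROC curve
#'
#' The default (non-specificity-optimized) operating mode of class
#' prediction balances sensitivity and specificity: the threshold at
#' the ROC point where the true-positive rate is closest to one minus
#' the false-positive rate.
#'
#' @param roc a [roc_curve()].
#' @return list with `threshold`, `tpr`, `fpr` at the balanced point.
#' @seealso [steepest_threshold()] for the specificity-optimized mode.
#' @export
equal_error_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  p <- roc$points[-1, , drop = FALSE]  # skip the (0,0) sentinel at +Inf
  i <- which.min(abs(p$tpr - (1 - p$fpr)))
  list(threshold = p$threshold[i], tpr = p$tpr[i], fpr = p$fpr[i])
}

#' Multi-label screening against per-class thresholds
#'
#' Assigns each case to every class whose predicted response reaches that
#' class's threshold, and categorizes the outcome as `none` (screened
#' out), `unique` (single CoD) or `multiple`.
#'
#' @param responses matrix (cases x classes) of predicted responses.
#' @param thresholds named numeric vector of per-class thresholds (fitted
#'   on training data only).
#' @return A list of class `screening_result`: `assigned` (list of class
#'   vectors per case), `outcome` (factor none/unique/multiple), and
#'   `counts` (table of outcomes).
#' @export
threshold_screen <- function(responses, thresholds) {
  responses <- rbind(responses)
  classes <- colnames(responses)
  if (is.null(classes)) stopf("responses must have class names as colnames")
  if (is.null(names(thresholds)) || !setequal(names(thresholds), classes)) {
    stopf("thresholds must be named with exactly the response classes")
  }
  thresholds <- thresholds[classes]
  hit <- sweep(responses, 2, thresholds, ">=")
  assigned <- apply(hit, 1, function(h) classes[h], simplify = FALSE)
  n_hit <- rowSums(hit)
  outcome <- factor(ifelse(n_hit == 0, "none", ifelse(n_hit == 1, "unique", "multiple")),
                    levels = c("none", "unique", "multiple"))
  structure(list(assigned = assigned, outcome = outcome,
                 counts = table(outcome), thresholds = thresholds),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  n <- length(x$outcome)
  cat(sprintf("<screening_result> %d cases: %d none (%d%%), %d unique (%d%%), %d multiple (%d%%)\n",
              n, x$counts["none"], round_half_up(100 * x$counts["none"] / n),
              x$counts["unique"], round_half_up(100 * x$counts["unique"] / n),
              x$counts["multiple"], round_half_up(100 * x$counts["multiple"] / n)))
  invisible(x)
}

#' Diagnostic metrics from a one-vs-rest confusion matrix
#'
#' Positive/negative predictive value, sensitivity, specificity and
#' accuracy as percentages rounded half-up to one decimal, the precision
#' used in clinical summary tables. Zero denominators yield `NA` rather
#' than errors.
#'
#' @param tp,fp,fn,tn non-negative confusion counts; `tp + fn` (class
#'   size) and `tn + fp` (complement size) must be positive.
#' @return A one-row data.frame with `tp`, `fp`, `fn`, `tn`, `ppv`,
#'   `npv`, `sensitivity`, `specificity`, `accuracy`.
#' @examples
#' confusion_metrics(16, 5, 9, 1040)  # 76.2 / 99.1 / 64.0 / 99.5 / 98.7
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stopf("confusion counts must be non-negative integers")
  }
  if (tp + fn <= 0) stopf("class size tp + fn must be positive")
  if (tn + fp <= 0) stopf("complement size tn + fp must be positive")
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den, 1) else NA_real_
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn),
             sensitivity = pct(tp, tp + fn), specificity = pct(tn, tn + fp),
             accuracy = pct(tp + tn, tp + fp + fn + tn))
}

#' Overall true-positive rate across groups
#'
#' @param true_positives per-group correct prediction counts.
#' @param group_sizes per-group case counts (same order).
#' @return overall rate as a whole-number percentage (rounded half-up).
#' @examples
#' overall_rates(c(45, 744, 666, 696, 31), c(75, 1039, 900, 1022, 176))  # 68
#' @export
overall_rates <- function(true_positives, group_sizes) {
  if (length(true_positives) != length(group_sizes)) {
    stopf("counts and sizes differ in length")
  }
  if (any(true_positives > group_sizes)) stopf("counts cannot exceed group sizes")
  round_half_up(100 * sum(true_positives) / sum(group_sizes))
}

#' Review contributing causes of death among false positives
#'
#' For each predicted class, the fraction of its false-positive cases
#' whose recorded contributing-CoD codes include that class: an estimate
#' of how often a "false" screening signal reflects a genuine but
#' non-primary condition.
#'
#' @param predicted_class character/factor of predicted class per
#'   false-positive case.
#' @param contributing list of character vectors (possibly empty) of
#'   contributing CoD codes per case, aligned with `predicted_class`.
#' @return data.frame with `class`, `n_false_positive`, `n_matching`,
#'   `match_pct` (percent, half-up to whole numbers; 0 with a note when a
#'   class has no false positives).
#' @export
fp_contributing_review <- function(predicted_class, contributing) {
  predicted_class <- as.character(predicted_class)
  if (length(predicted_class) != length(contributing)) {
    stopf("predicted_class and contributing differ in length")
  }
  classes <- unique(predicted_class)
  rows <- lapply(classes, function(cl) {
    idx <- predicted_class == cl
    match_n <- sum(vapply(contributing[idx], function(cc) cl %in% cc, logical(1)))
    n <- sum(idx)
    data.frame(class = cl, n_false_positive = n, n_matching = match_n,
               match_pct = if (n > 0) round_half_up(100 * match_n / n) else 0)
  })
  out <- do.call(rbind, rows)
  if (all(out$n_matching == 0)) {
    attr(out, "note") <- "n=0 matches: no contributing codes matched any predicted class"
  }
  out
}
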