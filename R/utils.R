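#' codscreen: cause-of-death screening from postmortem metabolomics
#'
#' Latent-variable screening of autopsy cases into cause-of-death groups
#' from LC-HRMS feature tables: preprocessing (retention-time filter,
#' probabilistic quotient normalization, log/unit-variance scaling),
#' NIPALS PCA/PLS/OPLS-DA with outlier and confounder screening, and
#' specificity-optimized ROC-threshold classification, plus a synthetic
#' cohort generator with planted ground truth.
#'
#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero to a fixed number of decimals
#'
#' Decimal rounding with ties going up (0.5 -> 1), matching how percentages
#' are conventionally printed in clinical tables, rather than the IEEE
#' round-half-even rule used by [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.5, 1.25, 67.93), c(0, 1, 0))
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() with sprintf-style formatting, no call in the condition
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All package-internal randomness funnels through
# this so that pipelines are reproducible from a single integer.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Stratified fold assignment: round-robin within each stratum after a
# seeded shuffle. Returns an integer vector of fold labels in 1..n_folds.
make_folds <- function(strata, n_folds, seed = 1L) {
  n <- length(strata)
  folds <- integer(n)
  with_seed(seed, {
    for (g in unique(strata)) {
      idx <- which(strata == g)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x) && x > 0
}
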