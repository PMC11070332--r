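#' Per-group PCA outlier detection
#'
#' For each CoD group, fits a PCA on that group's log/UV-transformed data
#' and flags a case as an outlier only when it exceeds both the
#' Hotelling's T2 (severe) and DModX (moderate) critical values at the
#' given significance level. Groups smaller than `min_cases` are skipped
#' with a warning.
#'
#' @param table a [feature_table()] of normalized intensities.
#' @param groups factor of CoD labels aligned with the table's cases.
#' @param n_components PCA components per group model (default 2).
#' @param alpha significance level for both criteria (default 0.05).
#' @param min_cases minimum group size to attempt a model (default 10).
#' @return A list of class `outlier_report`: `outliers` (named list of
#'   case-id vectors per group), `flagged_t2`, `flagged_dmodx` (per
#'   group), and `all_outliers` (the union).
#' @export
detect_group_outliers <- function(table, groups, n_components = 2,
                                  alpha = 0.05, min_cases = 10) {
  stopifnot(inherits(table, "feature_table"))
  groups <- factor(groups)
  if (length(groups) != nrow(table$intensities)) {
    stopf("groups must have one label per case")
  }
  out <- t2f <- dmf <- stats::setNames(vector("list", nlevels(groups)), levels(groups))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < min_cases) {
      warnf("group '%s' has %d cases (< %d): outlier screening skipped",
            g, length(idx), min_cases)
      out[[g]] <- character(0); t2f[[g]] <- character(0); dmf[[g]] <- character(0)
      next
    }
    sub <- ft_subset(table, cases = idx)
    tr <- log_uv_transform(sub)
    model <- fit_pca(tr$matrix, n_components = min(n_components, length(idx) - 2L))
    t2 <- hotelling_t2(model, alpha = alpha)
    dm <- dmodx(model, alpha = alpha)
    ids <- sub$case_ids
    t2f[[g]] <- ids[t2$flagged]
    dmf[[g]] <- ids[dm$flagged]
    out[[g]] <- ids[t2$flagged & dm$flagged]
  }
  structure(list(outliers = out, flagged_t2 = t2f, flagged_dmodx = dmf,
                 all_outliers = unlist(out, use.names = FALSE)),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report>\n")
  for (g in names(x$outliers)) {
    cat(sprintf("  %s: %d excluded (T2: %d, DModX: %d)\n", g,
                length(x$outliers[[g]]), length(x$flagged_t2[[g]]),
                length(x$flagged_dmodx[[g]])))
  }
  invisible(x)
}

#' Screen features for association with case characteristics
#'
#' For every CoD group and covariate, fits a PLS model (PLS-DA for sex)
#' of the group's log/UV-transformed features against the covariate. A
#' feature is excluded for a covariate when its |p(corr)| exceeds
#' `threshold` in at least `min_groups` of the groups whose model was
#' produced; if fewer than `min_groups` groups produce a model for a
#' covariate, nothing is excluded for it (a covariate that cannot explain
#' the metabolome in most groups is not treated as a confounder).
#'
#' @param table a [feature_table()] of normalized intensities, outlier
#'   cases already removed.
#' @param metadata data.frame with `case_id` plus the covariate columns;
#'   rows matched to the table by `case_id`.
#' @param groups factor of CoD labels aligned with the table's cases.
#' @param covariates covariate names to screen (default age, sex, bmi,
#'   pmi, run_date).
#' @param threshold |p(corr)| exclusion threshold (default 0.5).
#' @param min_groups minimum number of groups surpassing the threshold
#'   (default 3).
#' @param ... passed to [fit_pls()] (folds, caps, seed).
#' @return A list of class `confounder_report`: `excluded_by_covariate`
#'   (named list of feature-id vectors), `excluded` (unique union),
#'   `valid_models` (logical matrix group x covariate), and `p_corr`
#'   (list of per-group p(corr) matrices).
#' @export
screen_confounders <- function(table, metadata, groups,
                               covariates = c("age", "sex", "bmi", "pmi", "run_date"),
                               threshold = 0.5, min_groups = 3, ...) {
  stopifnot(inherits(table, "feature_table"))
  groups <- factor(groups)
  missing_cov <- setdiff(covariates, colnames(metadata))
  if (length(missing_cov)) {
    stopf("unknown covariate(s): %s", paste(missing_cov, collapse = ", "))
  }
  md <- metadata[match(table$case_ids, metadata$case_id), , drop = FALSE]
  if (anyNA(md$case_id)) stopf("metadata is missing some cases in the table")

  k <- length(table$feature_ids)
  valid <- matrix(FALSE, nlevels(groups), length(covariates),
                  dimnames = list(levels(groups), covariates))
  pcorr_store <- list()
  exceed <- array(FALSE, dim = c(k, nlevels(groups), length(covariates)),
                  dimnames = list(table$feature_ids, levels(groups), covariates))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- ft_subset(table, cases = idx)
    tr <- suppressWarnings(log_uv_transform(sub))
    pcm <- matrix(NA_real_, k, length(covariates),
                  dimnames = list(table$feature_ids, covariates))
    for (cv in covariates) {
      yv <- md[[cv]][idx]
      y <- if (is.character(yv) || is.factor(yv)) factor(yv) else as.numeric(yv)
      model <- fit_pls(tr$matrix, y, ...)
      if (model$valid) {
        valid[g, cv] <- TRUE
        pcm[tr$feature_ids, cv] <- model$p_corr
        exceed[tr$feature_ids, g, cv] <- abs(model$p_corr) > threshold
      }
    }
    pcorr_store[[g]] <- pcm
  }
  excluded_by <- stats::setNames(vector("list", length(covariates)), covariates)
  for (cv in covariates) {
    if (sum(valid[, cv]) < min_groups) {
      excluded_by[[cv]] <- character(0)
      next
    }
    hits <- rowSums(matrix(exceed[, , cv], nrow = k), na.rm = TRUE)
    excluded_by[[cv]] <- table$feature_ids[hits >= min_groups]
  }
  structure(list(excluded_by_covariate = excluded_by,
                 excluded = unique(unlist(excluded_by, use.names = FALSE)),
                 valid_models = valid, p_corr = pcorr_store,
                 threshold = threshold, min_groups = min_groups),
            class = "confounder_report")
}

#' @export
print.confounder_report <- function(x, ...) {
  cat("<confounder_report>\n")
  for (cv in names(x$excluded_by_covariate)) {
    cat(sprintf("  %s: %d excluded (models in %d group(s))\n", cv,
                length(x$excluded_by_covariate[[cv]]), sum(x$valid_models[, cv])))
  }
  cat(sprintf("  unique features excluded: %d\n", length(x$excluded)))
  invisible(x)
}

#' Refine an OPLS-DA model by VIP feature selection
#'
#' Retains features with VIP at or above `vip_cut` in an initial model
#' and refits the OPLS-DA on the retained columns. Since the mean of
#' squared VIP values is 1, at least one feature always survives the
#' default cut.
#'
#' @param X transformed matrix used for the initial fit.
#' @param groups class factor.
#' @param vip_cut VIP retention threshold (default 1.0).
#' @param initial optionally, an already fitted [fit_oplsda()] model for
#'   `X` to avoid refitting.
#' @param ... passed to [fit_oplsda()].
#' @return list of class `vip_refinement`: `retained` (feature ids),
#'   `initial` and `refit` models.
#' @export
vip_refine <- function(X, groups, vip_cut = 1.0, initial = NULL, ...) {
  X <- as.matrix(X)
  initial <- initial %||% fit_oplsda(X, groups, ...)
  keep <- initial$vip >= vip_cut
  if (sum(keep) < 2L) {
    stopf("fewer than 2 features at VIP >= %g; lower the cut", vip_cut)
  }
  refit <- fit_oplsda(X[, keep, drop = FALSE], groups, ...)
  structure(list(retained = initial$feature_ids[keep],
                 vip_cut = vip_cut, initial = initial, refit = refit),
            class = "vip_refinement")
}

#' @export
print.vip_refinement <- function(x, ...) {
  cat(sprintf("<vip_refinement> VIP >= %g: %d of %d features retained\n",
              x$vip_cut, length(x$retained), x$initial$n_features))
  cat(sprintf("  initial R2 = %.3f, Q2 = %.3f; refit R2 = %.3f, Q2 = %.3f\n",
              x$initial$r2, x$initial$q2, x$refit$r2, x$refit$q2))
  invisible(x)
}
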