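#' Pipeline configuration
#'
#' Collects every tunable threshold of the screening workflow with its
#' default: retention-time window 90-660 s, outlier significance
#' alpha = 0.05, |p(corr)| confounder cut 0.5 in at least 3 groups,
#' VIP cut 1.0, ROC selection region TPR > 0.3 / FPR < 0.1, 7-fold
#' cross-validation, 75% training split.
#'
#' @param ... overrides of any default listed above.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(rt_min = 90, rt_max = 660,
              outlier_alpha = 0.05, outlier_components = 5,
              pcorr_threshold = 0.5, min_groups = 3,
              vip_cut = 1.0,
              roc_tpr_min = 0.3, roc_fpr_max = 0.1,
              n_folds = 7, max_ortho = 10, q2_min_inc = 0.01,
              train_fraction = 0.75, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return the path (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Stratified train/test split
#'
#' Randomly assigns `train_fraction` of each CoD group's cases (rounded
#' to the nearest case) to the training partition and the remainder to
#' the test partition; disjoint, exhaustive, deterministic for a fixed
#' seed.
#'
#' @param cohort a [generate_cohort()] result, or any list with
#'   `features` (a [feature_table()]) and `metadata` (with `case_id` and
#'   `group`).
#' @param train_fraction fraction per group assigned to training
#'   (default 0.75).
#' @param seed integer seed.
#' @return list with `train` and `test`, each a cohort-like list
#'   (features, metadata, and truth subset when present).
#' @export
split_train_test <- function(cohort, train_fraction = 0.75, seed = 1L) {
  md <- cohort$metadata
  groups <- factor(md$group)
  if (any(table(groups) < 4L)) {
    stopf("every group needs at least 4 cases to split %d%%/%d%%",
          round(100 * train_fraction), round(100 * (1 - train_fraction)))
  }
  train_idx <- integer(0)
  with_seed(seed, {
    for (g in levels(groups)) {
      idx <- which(groups == g)
      n_train <- round(train_fraction * length(idx))
      n_train <- max(1L, min(length(idx) - 1L, n_train))
      train_idx <- c(train_idx, sort(sample(idx, n_train)))
    }
  })
  take <- function(idx) {
    ids <- md$case_id[idx]
    out <- list(features = ft_subset(cohort$features, cases = ids),
                metadata = md[idx, , drop = FALSE])
    if (!is.null(cohort$truth)) {
      out$truth <- list(feature_roles = cohort$truth$feature_roles,
                        outlier = cohort$truth$outlier[ids],
                        dilution = cohort$truth$dilution[ids])
    }
    out
  }
  list(train = take(sort(train_idx)),
       test = take(setdiff(seq_len(nrow(md)), train_idx)))
}

#' Fit the full training-side screening workflow
#'
#' Runs the study's stages in order on the training partition:
#' retention-time filtering, PQN, per-group PCA outlier exclusion,
#' per-covariate PLS confounder screening, initial OPLS-DA, VIP
#' refinement, training-set class prediction (outlier cases re-included
#' at prediction time), per-class ROC curves and specificity-optimized
#' thresholds. Outliers are excluded from all model fitting but kept in
#' the training prediction counts, since they are genuine cases a
#' screening tool must handle.
#'
#' @param train a cohort-like list (`features`, `metadata`) from
#'   [split_train_test()].
#' @param config a [pipeline_config()].
#' @param covariates covariates screened as potential confounders.
#' @return An object of class `cod_artifacts` holding the fitted
#'   preprocessing parameters, models, thresholds and a `report` of
#'   per-stage counts and training metrics.
#' @export
run_training <- function(train, config = pipeline_config(),
                         covariates = c("age", "sex", "bmi", "pmi", "run_date")) {
  stopifnot(inherits(config, "pipeline_config"))
  md <- train$metadata
  groups <- factor(md$group)
  report <- list(n_cases_in = nrow(md), n_features_in = ncol(train$features$intensities))

  ## stage 1: retention-time filter + PQN
  ft <- filter_retention_time(train$features, config$rt_min, config$rt_max)
  report$n_features_rt <- ncol(ft$intensities)
  pqn <- pqn_normalize(ft)
  norm <- pqn$normalized

  ## stage 2: per-group PCA outlier exclusion
  outliers <- detect_group_outliers(norm, groups,
                                    n_components = config$outlier_components,
                                    alpha = config$outlier_alpha)
  keep_cases <- !(norm$case_ids %in% outliers$all_outliers)
  report$n_outliers <- sum(!keep_cases)
  report$outliers_by_group <- vapply(outliers$outliers, length, integer(1))
  fit_table <- ft_subset(norm, cases = keep_cases)
  fit_groups <- groups[keep_cases]

  ## stage 3: confounder screening
  confounders <- screen_confounders(fit_table, md, fit_groups,
                                    covariates = covariates,
                                    threshold = config$pcorr_threshold,
                                    min_groups = config$min_groups,
                                    n_folds = config$n_folds,
                                    cv_seed = config$seed)
  keep_features <- setdiff(fit_table$feature_ids, confounders$excluded)
  report$n_confounder_excluded <- length(confounders$excluded)
  report$n_features_retained <- length(keep_features)
  fit_table <- ft_subset(fit_table, features = keep_features)

  ## stage 4: transform + initial OPLS-DA + VIP refinement
  transform <- log_uv_transform(fit_table)
  refinement <- vip_refine(transform$matrix, fit_groups,
                           vip_cut = config$vip_cut,
                           n_folds = config$n_folds,
                           max_ortho = config$max_ortho,
                           q2_min_inc = config$q2_min_inc,
                           cv_seed = config$seed)
  model <- refinement$refit
  report$initial_model <- c(r2 = refinement$initial$r2, q2 = refinement$initial$q2,
                            n_ortho = refinement$initial$n_ortho)
  report$refit_model <- c(r2 = model$r2, q2 = model$q2, n_ortho = model$n_ortho)
  report$n_features_vip <- length(refinement$retained)

  artifacts <- structure(
    list(classes = levels(groups),
         rt_min = config$rt_min, rt_max = config$rt_max,
         pqn_reference = pqn$reference_spectrum,
         transform = transform[c("centers", "scales", "pseudo", "feature_ids")],
         model = model, vip_retained = refinement$retained,
         config = unclass(config)),
    class = "cod_artifacts"
  )

  ## stage 5: training-set prediction (all cases, outliers re-included)
  responses <- predict_cohort(artifacts, list(features = train$features, metadata = md))
  predicted <- classify_argmax(responses)
  report$training_prediction <- prediction_table(predicted, groups)
  report$training_overall_tp_pct <- overall_rates(
    report$training_prediction$true_positive, report$training_prediction$n)

  ## stage 6: per-class ROC + specificity-optimized thresholds.
  ## Thresholds must transfer to cases the model has never seen, so the
  ## ROC is built from cross-validated responses: each fitting case is
  ## predicted by a model refitted without its fold; the outlier cases
  ## (never fitted) keep their full-model predictions.
  Xv <- transform$matrix[, refinement$retained, drop = FALSE]
  cv_resp <- cv_responses(Xv, fit_groups, model, config)
  resp_thr <- responses
  fit_ids <- rownames(Xv)
  resp_thr[match(fit_ids, md$case_id), ] <- cv_resp
  rocs <- lapply(levels(groups), function(g) roc_curve(resp_thr[, g], groups == g))
  names(rocs) <- levels(groups)
  thr <- lapply(rocs, steepest_threshold,
                tpr_min = config$roc_tpr_min, fpr_max = config$roc_fpr_max)
  artifacts$thresholds <- vapply(thr, `[[`, numeric(1), "threshold")
  artifacts$threshold_points <- data.frame(
    class = names(thr),
    tpr = vapply(thr, `[[`, numeric(1), "tpr"),
    fpr = vapply(thr, `[[`, numeric(1), "fpr"))
  report$training_auc <- vapply(rocs, `[[`, numeric(1), "auc")
  train_screen <- threshold_screen(resp_thr, artifacts$thresholds)
  report$training_screen <- screening_metrics(train_screen, groups, levels(groups))
  artifacts$report <- report
  artifacts
}

# Cross-validated class responses: refit the final model's structure
# (same feature set, component counts) without each fold and predict the
# held-out cases.
cv_responses <- function(X, groups, model, config) {
  Y <- stats::model.matrix(~ 0 + groups)
  colnames(Y) <- levels(groups)
  folds <- make_folds(as.character(groups), config$n_folds, seed = config$seed)
  out <- matrix(NA_real_, nrow(X), ncol(Y), dimnames = list(rownames(X), colnames(Y)))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    core <- opls_core(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                      model$n_ortho, model$n_pred)
    out[!tr, ] <- opls_core_predict(core, X[!tr, , drop = FALSE])
  }
  out
}

#' @export
print.cod_artifacts <- function(x, ...) {
  cat(sprintf("<cod_artifacts> %d classes, %d features after screening, %d at VIP cut\n",
              length(x$classes), length(x$transform$feature_ids),
              length(x$vip_retained)))
  cat(sprintf("  final model: R2 = %.3f, Q2 = %.3f; training overall TP rate = %d%%\n",
              x$model$r2, x$model$q2, x$report$training_overall_tp_pct))
  invisible(x)
}

# Preprocess a cohort with stored artifacts and predict class responses.
predict_cohort <- function(artifacts, cohort) {
  ft <- cohort$features
  pos <- match(names(artifacts$pqn_reference), ft$feature_ids)
  if (anyNA(pos)) {
    stopf("feature mismatch: cohort lacks %d feature(s) of the fitted pipeline, e.g. %s",
          sum(is.na(pos)),
          paste(utils::head(names(artifacts$pqn_reference)[is.na(pos)], 5), collapse = ", "))
  }
  ft <- ft_subset(ft, features = pos)
  norm <- pqn_normalize(ft, reference = artifacts$pqn_reference)$normalized
  m <- apply_uv_transform(artifacts$transform, norm)
  predict_responses(artifacts$model, m[, artifacts$vip_retained, drop = FALSE])
}

prediction_table <- function(predicted, truth) {
  classes <- levels(factor(truth))
  data.frame(
    group = classes,
    n = as.integer(table(truth)[classes]),
    true_positive = vapply(classes, function(g) {
      sum(predicted == g & truth == g)
    }, integer(1)),
    false_positive = vapply(classes, function(g) {
      sum(predicted == g & truth != g)
    }, integer(1)),
    row.names = NULL)
}

screening_metrics <- function(screen, truth, classes) {
  assigned <- screen$assigned
  per_class <- lapply(classes, function(g) {
    in_class <- truth == g
    hit <- vapply(assigned, function(a) g %in% a, logical(1))
    confusion_metrics(tp = sum(hit & in_class), fp = sum(hit & !in_class),
                      fn = sum(!hit & in_class), tn = sum(!hit & !in_class))
  })
  metrics <- cbind(data.frame(group = classes), do.call(rbind, per_class))
  n <- length(truth)
  list(outcome_counts = screen$counts,
       outcome_pct = round_half_up(100 * as.numeric(screen$counts) / n),
       metrics = metrics,
       overall_sensitivity_pct = round_half_up(
         100 * sum(metrics$tp) / sum(metrics$tp + metrics$fn)),
       overall_specificity_pct = round_half_up(
         100 * sum(metrics$tn) / sum(metrics$tn + metrics$fp)))
}

#' Validate fitted artifacts on an independent test partition
#'
#' Applies the serialized training-side pipeline (PQN reference, log/UV
#' parameters, final OPLS-DA model, ROC thresholds) to a test partition
#' that took no part in any fitting, and reports argmax prediction
#' counts, per-class AUC, threshold-screening outcomes and per-class
#' diagnostic metrics. The artifacts are read-only: validation never
#' refits or updates them.
#'
#' @param test a cohort-like list from [split_train_test()].
#' @param artifacts a [run_training()] result (possibly reloaded with
#'   [load_artifacts()]).
#' @return A list of class `validation_report` with `prediction`
#'   (Table-2-style counts), `overall_tp_pct`, `auc` (per class, test),
#'   `training_auc` (for side-by-side comparison), `screen` (outcome
#'   counts, per-class metrics, overall sensitivity/specificity) and
#'   `fp_review` (contributing-CoD review of the false positives, when
#'   the metadata records contributing codes).
#' @export
run_validation <- function(test, artifacts) {
  stopifnot(inherits(artifacts, "cod_artifacts"))
  md <- test$metadata
  truth <- factor(md$group, levels = artifacts$classes)
  responses <- predict_cohort(artifacts, test)
  predicted <- classify_argmax(responses)
  pred_tab <- prediction_table(predicted, truth)
  rocs <- lapply(artifacts$classes, function(g) roc_curve(responses[, g], truth == g))
  names(rocs) <- artifacts$classes
  screen <- threshold_screen(responses, artifacts$thresholds)
  metrics <- screening_metrics(screen, truth, artifacts$classes)

  fp_review <- NULL
  if ("contributing" %in% colnames(md)) {
    fp_idx <- which(vapply(seq_along(screen$assigned), function(i) {
      any(screen$assigned[[i]] != as.character(truth[i]))
    }, logical(1)))
    if (length(fp_idx)) {
      fp_class <- unlist(lapply(fp_idx, function(i) {
        setdiff(screen$assigned[[i]], as.character(truth[i]))
      }))
      fp_case <- rep(fp_idx, vapply(fp_idx, function(i) {
        length(setdiff(screen$assigned[[i]], as.character(truth[i])))
      }, integer(1)))
      contrib <- strsplit(md$contributing[fp_case], ";", fixed = TRUE)
      fp_review <- fp_contributing_review(fp_class, contrib)
    }
  }
  structure(
    list(prediction = pred_tab,
         overall_tp_pct = overall_rates(pred_tab$true_positive, pred_tab$n),
         auc = vapply(rocs, `[[`, numeric(1), "auc"),
         training_auc = artifacts$report$training_auc,
         screen = metrics, fp_review = fp_review,
         responses = responses),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> overall TP rate = %d%%\n", x$overall_tp_pct))
  cat("  AUC (test):", paste(sprintf("%s %.2f", names(x$auc), x$auc), collapse = ", "), "\n")
  cat(sprintf("  screening: %s\n",
              paste(sprintf("%s %d%%", names(x$screen$outcome_counts), x$screen$outcome_pct),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize / restore fitted pipeline artifacts
#'
#' Artifacts are stored as structured JSON (full double precision) so
#' that screening can be reproduced without refitting.
#'
#' @param artifacts a [run_training()] result.
#' @param path file path (`.json`).
#' @return `save_artifacts` returns `path` invisibly; `load_artifacts`
#'   returns the restored `cod_artifacts`.
#' @export
save_artifacts <- function(artifacts, path) {
  stopifnot(inherits(artifacts, "cod_artifacts"))
  # 17 significant digits: doubles round-trip bit-exactly through JSON
  writeLines(jsonlite::serializeJSON(artifacts, digits = I(17)), path)
  invisible(path)
}

#' @rdname save_artifacts
#' @export
load_artifacts <- function(path) {
  out <- jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
  if (!inherits(out, "cod_artifacts")) stopf("'%s' does not contain pipeline artifacts", path)
  out
}
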