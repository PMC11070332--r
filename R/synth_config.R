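# Study-population targets per CoD group: sizes, median (Q1-Q3) of age,
# BMI and PMI, and percent female, as characterized for the five-group
# forensic cohort the generator emulates.
cod_group_targets <- function() {
  data.frame(
    group = c("acidosis", "drug_intoxication", "hanging", "ihd", "pneumonia"),
    n = c(100L, 1385L, 1200L, 1362L, 235L),
    age_med = c(62, 39, 45, 65, 63),
    age_q1 = c(55, 29, 30, 57, 55),
    age_q3 = c(68, 54, 60, 73, 71),
    pct_female = c(30, 35, 22, 20, 33),
    bmi_med = c(22.8, 27, 23.9, 26.4, 23),
    bmi_q1 = c(19.4, 23.11, 21.4, 23.4, 18.2),
    bmi_q3 = c(27.1, 31.2, 27, 30.4, 27.5),
    pmi_med = c(6, 5, 5, 6, 6),
    pmi_q1 = c(4, 4, 3, 4, 4),
    pmi_q3 = c(8, 7, 7, 8, 8),
    stringsAsFactors = FALSE
  )
}

#' Cause-of-death group levels
#'
#' Canonical ordering of the five CoD groups used throughout the package.
#' @return character vector of group names.
#' @export
cod_groups <- function() cod_group_targets()$group

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by [generate_cohort()]: group
#' sizes and covariate distributions of a five-group forensic autopsy
#' cohort, number of chromatographic features, planted group-discriminant
#' and covariate-confounded features, analytical-run (batch) structure,
#' per-sample dilution, and a small fraction of multivariate outlier cases.
#'
#' @param group_sizes named integer vector of cases per CoD group at full
#'   scale. Default: the five-group study population (100, 1385, 1200,
#'   1362, 235 for acidosis, drug intoxication, hanging, IHD, pneumonia).
#' @param scale fraction of the full group sizes to generate (default
#'   0.25, a reduced cohort in which every group retains enough cases for
#'   stable per-group diagnostics and 7-fold cross-validation; use
#'   `scale = 1` for a full-size cohort).
#' @param n_features total number of chromatographic features (default
#'   1321).
#' @param n_discriminant_per_group features carrying a planted
#'   group-specific abundance shift, per group (default 30).
#' @param n_confounded_per_covariate features carrying a planted linear
#'   dependence on each covariate (age, sex, BMI, PMI, run date; default
#'   25 each).
#' @param n_batches number of analytical runs (default 641); each case is
#'   assigned a run date uniformly.
#' @param dilution_log_sd standard deviation of per-sample log dilution
#'   factors (natural log scale, default 0.3).
#' @param batch_log_sd standard deviation of the per-run intensity offset
#'   shared by all features of a sample (default 0.1).
#' @param noise_log_sd residual log-intensity noise per measurement
#'   (default 0.6).
#' @param effect_size_log planted discriminant effect in natural-log
#'   intensity units (default 0.5).
#' @param effect_balance when TRUE (default), each group's discriminant
#'   effect is multiplied by `(max(group size) / group size)^0.75`, so
#'   the small CoD groups carry proportionally more distinct fingerprints.
#'   This emulates the empirical pattern that the rare groups (acidosis,
#'   pneumonia) are the most metabolically distinct, and keeps every
#'   class detectable under a shared multivariate model despite the heavy
#'   class imbalance.
#' @param confound_effect_log slope of confounded features on the
#'   standardized covariate, in log units (default 2.0, strong enough
#'   that the within-group |p(corr)| of a confounded feature clears the
#'   0.5 exclusion threshold in most groups).
#' @param n_latent_factors number of latent "metabolic state" factors
#'   generating correlated variation across features in every case
#'   (default 6); these emulate the dominant within-group principal
#'   components of real cohort data.
#' @param latent_loading_sd standard deviation of per-feature loadings on
#'   the latent factors (default 0.3, log units).
#' @param outlier_fraction fraction of cases planted as multivariate
#'   outliers (default 0.03).
#' @param outlier_score_shift magnitude of the latent-score displacement
#'   of outlier cases along two random factors (default 4 standard
#'   deviations; drives Hotelling's T2).
#' @param outlier_log_shift multiplicative log-shift applied to a random
#'   subset of features of each outlier case (default 2.0; drives DModX).
#' @param outlier_feature_fraction fraction of features perturbed per
#'   outlier case (default 0.15).
#' @param contributing_rate probability that a case carries a contributing
#'   CoD code from another group (default 0.15).
#' @param baseline_log_mean,baseline_log_sd distribution of per-feature
#'   baseline log intensities (defaults 11.5 and 1.0, i.e. raw peak areas
#'   around 1e5).
#' @param seed integer seed; a fixed seed yields a bit-identical cohort.
#' @return an object of class `synthetic_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(group_sizes = NULL, scale = 0.25,
                             n_features = 1321L,
                             n_discriminant_per_group = 30L,
                             n_confounded_per_covariate = 25L,
                             n_batches = 641L,
                             dilution_log_sd = 0.3,
                             batch_log_sd = 0.1,
                             noise_log_sd = 0.6,
                             effect_size_log = 0.5,
                             effect_balance = TRUE,
                             confound_effect_log = 2.0,
                             n_latent_factors = 6L,
                             latent_loading_sd = 0.3,
                             outlier_fraction = 0.03,
                             outlier_score_shift = 4,
                             outlier_log_shift = 2.0,
                             outlier_feature_fraction = 0.15,
                             contributing_rate = 0.15,
                             baseline_log_mean = 11.5,
                             baseline_log_sd = 1.0,
                             seed = 1L) {
  targets <- cod_group_targets()
  if (is.null(group_sizes)) {
    group_sizes <- stats::setNames(targets$n, targets$group)
  }
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% targets$group)) {
    stopf("group_sizes must be named with CoD groups: %s",
          paste(targets$group, collapse = ", "))
  }
  if (!is.numeric(scale) || scale <= 0 || scale > 1) {
    stopf("scale must be in (0, 1]")
  }
  sizes <- stats::setNames(pmax(1L, as.integer(round(group_sizes * scale))),
                           names(group_sizes))
  if (any(sizes < 1L)) stopf("all group sizes must be positive")
  for (nm in c("n_features", "n_discriminant_per_group",
               "n_confounded_per_covariate", "n_batches", "n_latent_factors")) {
    if (!is_count(get(nm))) stopf("%s must be a positive count", nm)
  }
  for (nm in c("dilution_log_sd", "batch_log_sd", "noise_log_sd",
               "outlier_log_shift")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0) stopf("%s must be a non-negative real", nm)
  }
  if (outlier_fraction < 0 || outlier_fraction >= 0.5) {
    stopf("outlier_fraction must lie in [0, 0.5)")
  }
  n_covariates <- 5L  # age, sex, bmi, pmi, run_date
  planted <- length(sizes) * n_discriminant_per_group +
    n_covariates * n_confounded_per_covariate
  if (planted > n_features) {
    stopf("planted feature counts (%d) exceed n_features (%d)", planted, n_features)
  }
  structure(
    list(group_sizes = sizes, scale = scale,
         n_features = as.integer(n_features),
         n_discriminant_per_group = as.integer(n_discriminant_per_group),
         n_confounded_per_covariate = as.integer(n_confounded_per_covariate),
         n_batches = as.integer(n_batches),
         dilution_log_sd = dilution_log_sd, batch_log_sd = batch_log_sd,
         noise_log_sd = noise_log_sd, effect_size_log = effect_size_log,
         effect_balance = isTRUE(effect_balance),
         confound_effect_log = confound_effect_log,
         n_latent_factors = as.integer(n_latent_factors),
         latent_loading_sd = latent_loading_sd,
         outlier_fraction = outlier_fraction,
         outlier_score_shift = outlier_score_shift,
         outlier_log_shift = outlier_log_shift,
         outlier_feature_fraction = outlier_feature_fraction,
         contributing_rate = contributing_rate,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat("  group sizes:", paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                              collapse = ", "), "\n")
  cat(sprintf("  features: %d (%d discriminant/group, %d confounded/covariate)\n",
              x$n_features, x$n_discriminant_per_group, x$n_confounded_per_covariate))
  cat(sprintf("  batches: %d, outlier fraction: %.3f, seed: %d\n",
              x$n_batches, x$outlier_fraction, x$seed))
  invisible(x)
}

#' Read or write a synthetic-cohort configuration as YAML
#'
#' @param config a [synthetic_config()].
#' @param path file path.
#' @return `write_synthetic_config` returns `path` invisibly;
#'   `read_synthetic_config` returns a `synthetic_config`.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  lst <- unclass(config)
  lst$group_sizes <- as.list(lst$group_sizes)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  lst <- yaml::read_yaml(path)
  gs <- unlist(lst$group_sizes)
  lst$group_sizes <- gs
  lst$scale <- 1  # sizes in the file are already the effective sizes
  do.call(synthetic_config, lst)
}
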