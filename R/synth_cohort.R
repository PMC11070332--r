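#' Generate a synthetic forensic metabolomics cohort
#'
#' Simulates a five-group autopsy cohort with the structure the screening
#' analysis assumes: group-specific covariate distributions (age, sex,
#' BMI, PMI) matching the study-population medians and quartiles,
#' analytical-run (batch) assignment, per-sample dilution, planted
#' group-discriminant features, covariate-confounded features, and a small
#' fraction of multivariate outlier cases. Every planted signal is
#' recorded in a ground-truth slot so downstream operations can be
#' validated against it.
#'
#' The log intensity of feature k in case i is
#' `baseline_k + effect * [k discriminant for group(i)] +
#'  beta * z_c(i) * [k confounded with covariate c] +
#'  sum_f L_kf s_if + batch_shift(run(i)) + log_dilution(i) + noise_ik`,
#' exponentiated to the raw intensity scale. The latent term `L s`
#' (dense loadings `L`, standard-normal per-case scores `s`) provides the
#' correlated inter-individual variation that dominates the principal
#' components of real cohort data. Outlier cases combine an extreme
#' displacement of two latent scores (a severe, in-model-plane deviation
#' that drives Hotelling's T2) with a multiplicative inflation of a
#' random feature subset (a moderate, off-plane deviation that drives
#' DModX), so that both diagnostics respond.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `synthetic_cohort`: a list with
#'   \describe{
#'     \item{features}{a [feature_table()] of raw intensities;}
#'     \item{metadata}{a data.frame with `case_id`, `group`, `age`, `sex`,
#'       `bmi`, `pmi`, `run_date` (integer batch index) and `contributing`
#'       (semicolon-joined contributing CoD codes, possibly empty);}
#'     \item{truth}{a list with `feature_roles` (per-feature: `"null"`,
#'       `"discriminant:<group>"` or `"confounded:<covariate>"`),
#'       `outlier` (per-case logical) and `dilution` (per-case true
#'       dilution factor).}
#'   }
#' @examples
#' cfg <- synthetic_config(scale = 0.02, n_features = 60, seed = 7)
#' coh <- generate_cohort(cfg)
#' table(coh$metadata$group)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stopf("`config` must be a synthetic_config object")
  }
  targets <- cod_group_targets()
  sizes <- config$group_sizes[targets$group[targets$group %in% names(config$group_sizes)]]
  groups_used <- names(sizes)
  n <- sum(sizes)
  k <- config$n_features
  covs <- c("age", "sex", "bmi", "pmi", "run_date")

  with_seed(config$seed, {
    ## --- cases and covariates -------------------------------------------
    group <- factor(rep(groups_used, times = sizes), levels = groups_used)
    tg <- targets[match(group, targets$group), ]
    draw_lognorm <- function(med, q1, q3) {
      sdlog <- log(q3 / q1) / (2 * stats::qnorm(0.75))
      exp(stats::rnorm(n, mean = log(med), sd = sdlog))
    }
    age <- draw_lognorm(tg$age_med, tg$age_q1, tg$age_q3)
    bmi <- draw_lognorm(tg$bmi_med, tg$bmi_q1, tg$bmi_q3)
    pmi <- draw_lognorm(tg$pmi_med, tg$pmi_q1, tg$pmi_q3)
    sex <- ifelse(stats::runif(n) < tg$pct_female / 100, "F", "M")
    run_date <- sample.int(config$n_batches, n, replace = TRUE)
    contributing <- vapply(seq_len(n), function(i) {
      if (length(groups_used) > 1L && stats::runif(1) < config$contributing_rate) {
        sample(setdiff(groups_used, as.character(group[i])), 1L)
      } else ""
    }, character(1))

    ## --- feature roles ---------------------------------------------------
    roles <- rep("null", k)
    pool <- seq_len(k)
    take <- function(m) {
      got <- pool[seq_len(m)]
      pool <<- pool[-seq_len(m)]
      got
    }
    pool <- sample(pool)  # shuffle so planted features are spread over ids
    for (g in groups_used) {
      roles[take(config$n_discriminant_per_group)] <- paste0("discriminant:", g)
    }
    for (cv in covs) {
      roles[take(config$n_confounded_per_covariate)] <- paste0("confounded:", cv)
    }

    ## --- log-intensity model --------------------------------------------
    baseline <- stats::rnorm(k, config$baseline_log_mean, config$baseline_log_sd)
    logx <- matrix(stats::rnorm(n * k, sd = config$noise_log_sd), n, k)
    logx <- sweep(logx, 2, baseline, "+")
    effect_mult <- if (isTRUE(config$effect_balance)) {
      (max(sizes) / sizes)^0.75
    } else {
      stats::setNames(rep(1, length(sizes)), names(sizes))
    }
    # each planted feature shifts up or down (fixed sign per feature), as
    # real metabolite fingerprints mix elevated and depressed abundances
    feature_sign <- sample(c(-1, 1), k, replace = TRUE)
    for (g in groups_used) {
      fk <- which(roles == paste0("discriminant:", g))
      in_g <- group == g
      if (length(fk)) {
        logx[in_g, fk] <- logx[in_g, fk] +
          rep(feature_sign[fk] * config$effect_size_log * effect_mult[[g]],
              each = sum(in_g))
      }
    }
    zstd <- function(v) as.numeric(scale(v))
    covariate_z <- cbind(age = zstd(log(age)), sex = zstd(sex == "F"),
                         bmi = zstd(log(bmi)), pmi = zstd(log(pmi)),
                         run_date = zstd(run_date))
    for (cv in covs) {
      fk <- which(roles == paste0("confounded:", cv))
      if (length(fk)) {
        logx[, fk] <- logx[, fk] +
          outer(covariate_z[, cv], feature_sign[fk] * config$confound_effect_log)
      }
    }
    ## latent correlated variation + outlier score displacement
    n_out <- round(config$outlier_fraction * n)
    outlier <- rep(FALSE, n)
    if (n_out > 0) outlier[sample.int(n, n_out)] <- TRUE
    if (config$n_latent_factors > 0) {
      L <- matrix(stats::rnorm(k * config$n_latent_factors,
                               sd = config$latent_loading_sd),
                  k, config$n_latent_factors)
      S <- matrix(stats::rnorm(n * config$n_latent_factors),
                  n, config$n_latent_factors)
      for (i in which(outlier)) {
        f2 <- sample.int(config$n_latent_factors, min(2L, config$n_latent_factors))
        S[i, f2] <- S[i, f2] + sample(c(-1, 1), length(f2), replace = TRUE) *
          config$outlier_score_shift
      }
      logx <- logx + tcrossprod(S, L)
    }

    batch_shift <- stats::rnorm(config$n_batches, sd = config$batch_log_sd)
    log_dilution <- stats::rnorm(n, sd = config$dilution_log_sd)
    # the run-level offset multiplies every feature of a sample, so the
    # effective (recoverable) dilution factor is their product
    log_dilution_total <- log_dilution + batch_shift[run_date]
    logx <- logx + log_dilution_total

    ## --- outlier residual inflation --------------------------------------
    if (any(outlier)) {
      n_pert <- max(1L, round(config$outlier_feature_fraction * k))
      for (i in which(outlier)) {
        fk <- sample.int(k, n_pert)
        logx[i, fk] <- logx[i, fk] + config$outlier_log_shift
      }
    }

    ## --- assemble --------------------------------------------------------
    case_ids <- sprintf("case_%04d", seq_len(n))
    feature_ids <- sprintf("F%04d", seq_len(k))
    ft <- feature_table(exp(logx),
                        feature_mz = round(stats::runif(k, 80, 800), 4),
                        feature_rt = round(stats::runif(k, 95, 655), 1),
                        case_ids = case_ids, feature_ids = feature_ids)
    metadata <- data.frame(case_id = case_ids, group = group,
                           age = age, sex = sex, bmi = bmi, pmi = pmi,
                           run_date = run_date, contributing = contributing,
                           stringsAsFactors = FALSE)
    structure(
      list(features = ft, metadata = metadata,
           truth = list(feature_roles = stats::setNames(roles, feature_ids),
                        outlier = stats::setNames(outlier, case_ids),
                        dilution = stats::setNames(exp(log_dilution_total), case_ids)),
           config = config),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases x %d features\n",
              nrow(x$features$intensities), ncol(x$features$intensities)))
  print(table(x$metadata$group))
  cat(sprintf("  planted outliers: %d\n", sum(x$truth$outlier)))
  invisible(x)
}

#' Write or read a synthetic cohort as plain-text fixture files
#'
#' Writes `features.csv` (feature-per-row peak table), `metadata.csv`,
#' `truth_features.csv` and `truth_cases.csv` into a directory; reading
#' the directory back reconstructs the cohort field-for-field within
#' numeric print precision (15 significant digits).
#'
#' @param cohort a [generate_cohort()] result.
#' @param path directory to create/read.
#' @return `write_fixture` returns `path` invisibly; `read_fixture`
#'   returns a `synthetic_cohort` (without the generating config).
#' @export
write_fixture <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  old <- options(digits = 15); on.exit(options(old))
  write_feature_table(cohort$features, file.path(path, "features.csv"))
  utils::write.table(cohort$metadata, file.path(path, "metadata.csv"),
                     sep = ",", row.names = FALSE, quote = TRUE)
  utils::write.table(
    data.frame(feature_id = names(cohort$truth$feature_roles),
               role = cohort$truth$feature_roles),
    file.path(path, "truth_features.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(case_id = names(cohort$truth$outlier),
               outlier = cohort$truth$outlier,
               dilution = sprintf("%.15g", cohort$truth$dilution)),
    file.path(path, "truth_cases.csv"), sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(path) {
  need <- file.path(path, c("features.csv", "metadata.csv",
                            "truth_features.csv", "truth_cases.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) stopf("fixture file(s) missing: %s", paste(missing, collapse = ", "))
  ft <- read_feature_table(need[1])
  metadata <- utils::read.table(need[2], sep = ",", header = TRUE,
                                stringsAsFactors = FALSE)
  metadata$group <- factor(metadata$group, levels = unique(metadata$group))
  metadata$contributing[is.na(metadata$contributing)] <- ""
  tf <- utils::read.table(need[3], sep = ",", header = TRUE, stringsAsFactors = FALSE)
  tc <- utils::read.table(need[4], sep = ",", header = TRUE, stringsAsFactors = FALSE)
  structure(
    list(features = ft, metadata = metadata,
         truth = list(feature_roles = stats::setNames(tf$role, tf$feature_id),
                      outlier = stats::setNames(tc$outlier, tc$case_id),
                      dilution = stats::setNames(as.numeric(tc$dilution), tc$case_id)),
         config = NULL),
    class = "synthetic_cohort"
  )
}
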