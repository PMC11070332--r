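#' Cohort characteristics tests across CoD groups
#'
#' Kruskal-Wallis tests for the continuous covariates (age, BMI, PMI) and
#' a chi-squared test on the sex-by-group contingency table, with
#' Shapiro-Wilk normality p-values reported for the continuous covariates
#' as the gate justifying the non-parametric choice.
#'
#' @param metadata data.frame with columns `group`, `age`, `sex`, `bmi`,
#'   `pmi`.
#' @param continuous names of continuous covariates (default age, bmi,
#'   pmi).
#' @return data.frame with `covariate`, `test`, `p_value`,
#'   `shapiro_p` (NA for sex).
#' @export
characteristics_tests <- function(metadata,
                                  continuous = c("age", "bmi", "pmi")) {
  g <- factor(metadata$group)
  if (nlevels(g) < 2L) stopf("need at least 2 groups")
  if (any(table(g) == 0L)) stopf("empty group in metadata")
  rows <- lapply(continuous, function(cv) {
    v <- as.numeric(metadata[[cv]])
    sh <- tryCatch(stats::shapiro.test(if (length(v) > 5000) sample(v, 5000) else v)$p.value,
                   error = function(e) NA_real_)
    data.frame(covariate = cv, test = "kruskal-wallis",
               p_value = stats::kruskal.test(v, g)$p.value, shapiro_p = sh)
  })
  tab <- table(metadata$sex, g)
  rows <- c(rows, list(data.frame(
    covariate = "sex", test = "chi-squared",
    p_value = suppressWarnings(stats::chisq.test(tab)$p.value),
    shapiro_p = NA_real_)))
  do.call(rbind, rows)
}

#' Per-feature one-way ANOVA across CoD groups
#'
#' One-way analysis-of-variance F-test per feature on log-transformed
#' abundances; significance at p < 0.05 identifies metabolites with
#' altered abundance between groups. Features are skipped (p = NA, with
#' a warning) when some group has fewer than 2 cases.
#'
#' @param abundances numeric matrix (cases x features) of log-transformed
#'   abundances.
#' @param groups factor of group labels.
#' @return named numeric vector of p-values, one per feature.
#' @export
anova_features <- function(abundances, groups) {
  abundances <- as.matrix(abundances)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stopf("need at least 2 groups")
  if (any(table(groups) < 2L)) {
    warnf("group(s) with < 2 cases: ANOVA skipped for all features")
    return(stats::setNames(rep(NA_real_, ncol(abundances)), colnames(abundances)))
  }
  p <- apply(abundances, 2, function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    stats::anova(stats::lm(v ~ groups))[["Pr(>F)"]][1]
  })
  stats::setNames(p, colnames(abundances))
}

#' Hierarchical clustering of group-mean abundance profiles
#'
#' Agglomerative clustering with Euclidean distance and Ward linkage,
#' applied to a matrix of log-transformed, autoscaled abundances — both
#' on the rows (CoD groups) and the columns (metabolites), as used for
#' heatmap presentation of group averages. Merge heights are monotone
#' non-decreasing under Ward linkage.
#'
#' @param group_mean_matrix numeric matrix (groups x metabolites),
#'   log-transformed and autoscaled (each column mean-centered and
#'   divided by its standard deviation).
#' @param cluster_columns also cluster the metabolite dimension (default
#'   TRUE).
#' @return A list of class `cluster_result` with `rows` and (optionally)
#'   `columns`, each a list holding the `hclust` object, the `order` of
#'   leaves and a `newick` string of the merge tree.
#' @export
cluster_groups <- function(group_mean_matrix, cluster_columns = TRUE) {
  m <- as.matrix(group_mean_matrix)
  if (nrow(m) < 2L) stopf("need at least 2 rows to cluster")
  cl <- function(x) {
    hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
    list(hclust = hc, order = rownames(x)[hc$order] %||% hc$order,
         newick = hclust_to_newick(hc))
  }
  out <- list(rows = cl(m))
  if (cluster_columns) {
    if (ncol(m) < 2L) stopf("need at least 2 columns to cluster columns")
    out$columns <- cl(t(m))
  }
  structure(c(out, list(distance = "euclidean", linkage = "ward.D2")),
            class = "cluster_result")
}

# Newick export of a merge tree via ape.
hclust_to_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s distance, %s linkage\n", x$distance, x$linkage))
  cat("  row order:", paste(x$rows$order, collapse = ", "), "\n")
  invisible(x)
}

#' Annotate features against an m/z library
#'
#' Matches observed feature m/z values to a user-supplied library within
#' a part-per-million tolerance; multiple hits per feature are allowed
#' and all are reported.
#'
#' @param features a [feature_table()], or a data.frame with columns
#'   `feature_id` and `mz`.
#' @param library data.frame with unique `id`, optional `name`, and `mz`
#'   columns.
#' @param tolerance_ppm positive matching tolerance in ppm (default 5).
#' @return data.frame with `feature_id`, `library_id`, `observed_mz`,
#'   `library_mz`, `error_ppm` (signed); zero rows when nothing matches.
#' @export
match_mz <- function(features, library, tolerance_ppm = 5) {
  if (!is.numeric(tolerance_ppm) || tolerance_ppm <= 0) {
    stopf("tolerance_ppm must be positive")
  }
  if (inherits(features, "feature_table")) {
    features <- data.frame(feature_id = features$feature_ids, mz = features$feature_mz)
  }
  if (anyDuplicated(library$id)) stopf("library entry ids must be unique")
  hits <- lapply(seq_len(nrow(features)), function(i) {
    err <- (features$mz[i] - library$mz) / library$mz * 1e6
    j <- which(abs(err) <= tolerance_ppm)
    if (!length(j)) return(NULL)
    data.frame(feature_id = features$feature_id[i], library_id = library$id[j],
               observed_mz = features$mz[i], library_mz = library$mz[j],
               error_ppm = err[j])
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(feature_id = character(0), library_id = character(0),
                      observed_mz = numeric(0), library_mz = numeric(0),
                      error_ppm = numeric(0))
  }
  rownames(out) <- NULL
  out
}
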