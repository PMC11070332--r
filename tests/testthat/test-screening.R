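test_that("planted outliers are recovered by the dual T2/DModX rule", {
  cohort <- default_cohort()
  norm <- pqn_normalize(cohort$features)$normalized
  report <- suppressWarnings(
    detect_group_outliers(norm, cohort$metadata$group, n_components = 5))
  planted <- names(cohort$truth$outlier)[cohort$truth$outlier]
  clean_n <- nrow(norm$intensities) - length(planted)
  expect_gte(mean(planted %in% report$all_outliers), 0.8)
  expect_lte(sum(!(report$all_outliers %in% planted)) / clean_n, 0.01)
  # flagged-both is the intersection of the single-criterion flags
  for (g in names(report$outliers)) {
    expect_setequal(report$outliers[[g]],
                    intersect(report$flagged_t2[[g]], report$flagged_dmodx[[g]]))
  }
})

test_that("clean Gaussian groups are rarely flagged", {
  set.seed(12)
  rates <- replicate(10, {
    ft <- feature_table(matrix(exp(rnorm(60 * 80, 8, 0.5)), 60, 80),
                        seq_len(80) + 100, seq_len(80) + 100)
    rep <- detect_group_outliers(ft, rep("g", 60), n_components = 3)
    length(rep$all_outliers) / 60
  })
  expect_lte(mean(rates), 0.01)
})

test_that("a case flagged by one criterion only is not excluded", {
  cohort <- default_cohort()
  norm <- pqn_normalize(cohort$features)$normalized
  report <- suppressWarnings(
    detect_group_outliers(norm, cohort$metadata$group, n_components = 5))
  one_sided <- setdiff(unlist(report$flagged_t2), unlist(report$flagged_dmodx))
  expect_true(all(!one_sided %in% report$all_outliers))
  # too-small groups are skipped with a warning, not an error
  small <- ft_subset(norm, cases = 1:8)
  expect_warning(rep2 <- detect_group_outliers(small, rep("tiny", 8)), "skipped")
  expect_length(rep2$all_outliers, 0)
})

test_that("confounder screening applies the three-group rule", {
  # build five groups where a feature tracks the covariate in a
  # controllable number of groups
  build <- function(n_hit, n = 40, seed = 5) {
    set.seed(seed)
    groups <- factor(rep(paste0("g", 1:5), each = n))
    age <- rnorm(5 * n, 50, 10)
    k <- 30
    m <- matrix(rnorm(5 * n * k), 5 * n, k)
    # feature 1 follows age strongly in the first n_hit groups
    for (gi in seq_len(n_hit)) {
      idx <- groups == paste0("g", gi)
      m[idx, 1] <- 2 * scale(age[idx]) + rnorm(n, sd = 0.4)
    }
    ft <- feature_table(exp(m), seq_len(k) + 100, seq_len(k) + 100)
    md <- data.frame(case_id = ft$case_ids, age = age)
    list(ft = ft, md = md, groups = groups)
  }
  d3 <- build(3)
  rep3 <- screen_confounders(d3$ft, d3$md, d3$groups, covariates = "age",
                             n_folds = 5)
  expect_true(d3$ft$feature_ids[1] %in% rep3$excluded_by_covariate$age)
  d2 <- build(2)
  rep2 <- screen_confounders(d2$ft, d2$md, d2$groups, covariates = "age",
                             n_folds = 5)
  expect_false(d2$ft$feature_ids[1] %in% rep2$excluded_by_covariate$age)
  expect_error(screen_confounders(d3$ft, d3$md, d3$groups,
                                  covariates = "shoe_size"), "unknown covariate")
})

test_that("a covariate explaining variance in under three groups excludes nothing", {
  set.seed(6)
  n <- 40
  groups <- factor(rep(paste0("g", 1:5), each = n))
  k <- 25
  m <- matrix(rnorm(5 * n * k), 5 * n, k)
  sex <- rep("M", 5 * n)
  two <- groups %in% c("g1", "g2")
  sex[two] <- sample(c("F", "M"), sum(two), replace = TRUE)
  # in the two mixed-sex groups, features 1-4 track sex strongly
  for (j in 1:4) m[two, j] <- ifelse(sex[two] == "F", 2.5, -2.5) + rnorm(sum(two), sd = 0.5)
  ft <- feature_table(exp(m), seq_len(k) + 100, seq_len(k) + 100)
  md <- data.frame(case_id = ft$case_ids, sex = sex)
  rep <- screen_confounders(ft, md, groups, covariates = "sex", n_folds = 5)
  # models exist only where sex varies: fewer than three groups, so
  # nothing is excluded
  expect_lte(sum(rep$valid_models[, "sex"]), 2)
  expect_length(rep$excluded, 0)
})

test_that("planted confounders are excluded and null features retained", {
  pipe <- default_pipeline()
  cohort <- pipe$cohort
  roles <- cohort$truth$feature_roles
  excluded <- setdiff(names(roles), pipe$artifacts$transform$feature_ids)
  confounded <- names(roles)[startsWith(roles, "confounded")]
  null_features <- names(roles)[roles == "null"]
  expect_gte(mean(confounded %in% excluded), 0.8)
  expect_lte(mean(null_features %in% excluded), 0.05)
})

test_that("VIP refinement keeps at least one feature and a vip_cut of zero is a no-op", {
  d <- default_matrix()
  idx <- c(which(d$groups == "hanging")[1:30], which(d$groups == "ihd")[1:30])
  X <- d$x[idx, 1:120]
  g <- droplevels(d$groups[idx])
  ref0 <- vip_refine(X, g, vip_cut = 0, n_pred = 1, max_ortho = 2, cv_seed = 1)
  expect_identical(ref0$retained, colnames(X))
  # mean(VIP^2) = 1 implies some feature is always at or above 1
  expect_gte(length(vip_refine(X, g, vip_cut = 1, n_pred = 1, max_ortho = 2,
                               cv_seed = 1)$retained), 1)
})

test_that("VIP refinement does not cost predictive power when half the features are noise", {
  set.seed(9)
  g <- factor(rep(c("a", "b"), each = 30))
  signal <- matrix(rnorm(60 * 20), 60, 20)
  signal[g == "a", ] <- signal[g == "a", ] + 1.2
  X <- scale(cbind(signal, matrix(rnorm(60 * 20), 60, 20)))
  colnames(X) <- paste0("F", 1:40)
  ref <- vip_refine(X, g, n_pred = 1, max_ortho = 2, cv_seed = 2)
  expect_gte(ref$refit$q2, ref$initial$q2 - 0.02)
  # the retained set is dominated by true signal features
  expect_gt(mean(ref$retained %in% paste0("F", 1:20)), 0.8)
})
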