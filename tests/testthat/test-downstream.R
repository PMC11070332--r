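test_that("characteristics tests use the stated procedures", {
  md <- default_cohort()$metadata
  res <- characteristics_tests(md)
  expect_setequal(res$covariate, c("age", "bmi", "pmi", "sex"))
  expect_identical(res$test[res$covariate == "sex"], "chi-squared")
  expect_true(all(res$test[res$covariate != "sex"] == "kruskal-wallis"))
  # the generated group differences are detected decisively
  expect_lt(res$p_value[res$covariate == "age"], 1e-10)
  expect_lt(res$p_value[res$covariate == "sex"], 0.05)
  expect_error(characteristics_tests(data.frame(group = "a", age = 1,
                                                sex = "M", bmi = 1, pmi = 1)),
               "2 groups")
})

test_that("null covariates give non-significant tests at the nominal rate", {
  set.seed(30)
  hits <- replicate(50, {
    md <- data.frame(group = rep(c("a", "b", "c"), each = 40),
                     age = rlnorm(120, log(50), 0.3),
                     sex = sample(c("F", "M"), 120, replace = TRUE),
                     bmi = rlnorm(120, log(25), 0.2),
                     pmi = rlnorm(120, log(5), 0.4))
    all(characteristics_tests(md)$p_value > 0.05)
  })
  expect_gte(mean(hits), 0.7)
})

test_that("maximal association in a 2x2 table is detected", {
  md <- data.frame(group = rep(c("a", "b"), each = 10),
                   sex = rep(c("F", "M"), each = 10),
                   age = rnorm(20, 50), bmi = rnorm(20, 25), pmi = rnorm(20, 5))
  res <- characteristics_tests(md)
  expect_lt(res$p_value[res$covariate == "sex"], 0.01)
})

test_that("per-feature ANOVA matches the textbook F computation", {
  g <- factor(rep(c("a", "b", "c"), times = c(4, 5, 3)))
  set.seed(31)
  v <- rnorm(12) + c(0, 1, 2)[as.integer(g)]
  p <- anova_features(matrix(v, ncol = 1), g)
  # hand computation
  gm <- mean(v)
  ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  f <- (ssb / 2) / (ssw / 9)
  expect_equal(unname(p[1]), pf(f, 2, 9, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("ANOVA is powerful for shifted groups and calibrated under the null", {
  set.seed(32)
  g <- factor(rep(c("a", "b", "c"), each = 50))
  shifted <- rnorm(150) + ifelse(g == "b", 3, 0)
  expect_lt(anova_features(matrix(shifted, ncol = 1), g)[1], 1e-6)
  nulls <- anova_features(matrix(rnorm(150 * 1000), 150, 1000), g)
  expect_lt(suppressWarnings(ks.test(nulls, "punif"))$statistic, 0.1)
  # group with < 2 cases: skipped with a warning
  g2 <- factor(rep(c("a", "b", "c"), times = c(1, 6, 5)))
  expect_warning(p2 <- anova_features(matrix(rnorm(12), ncol = 1), g2), "< 2")
  expect_true(all(is.na(p2)))
})

test_that("Ward clustering merges duplicates first and matches a brute-force oracle", {
  m <- rbind(a = c(0, 0, 1), b = c(0, 0, 1), c = c(5, 5, 5), d = c(9, 1, 2))
  res <- cluster_groups(m, cluster_columns = FALSE)
  hc <- res$rows$hclust
  expect_identical(sort(hc$merge[1, ]), c(-2L, -1L))
  expect_equal(hc$height[1], 0)
  expect_true(all(diff(hc$height) >= 0))

  # exhaustive Ward objective oracle on 4-point instances: at each step,
  # merge the pair with the smallest increase in within-cluster variance
  ward_oracle <- function(x) {
    clusters <- lapply(seq_len(nrow(x)), function(i) i)
    merges <- list()
    while (length(clusters) > 1) {
      best <- NULL; best_cost <- Inf
      for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
        a <- x[clusters[[i]], , drop = FALSE]
        b <- x[clusters[[j]], , drop = FALSE]
        cost <- nrow(a) * nrow(b) / (nrow(a) + nrow(b)) *
          sum((colMeans(a) - colMeans(b))^2)
        if (cost < best_cost) { best <- c(j, i); best_cost <- cost }
      }
      merges <- c(merges, list(sort(unlist(clusters[best]))))
      clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
      clusters[[best[2]]] <- NULL
    }
    merges
  }
  hclust_merge_sets <- function(hc) {
    sets <- list()
    members <- list()
    for (i in seq_len(nrow(hc$merge))) {
      get_members <- function(v) {
        if (v < 0) -v else members[[v]]
      }
      members[[i]] <- sort(c(get_members(hc$merge[i, 1]),
                             get_members(hc$merge[i, 2])))
      sets <- c(sets, list(members[[i]]))
    }
    sets
  }
  set.seed(33)
  for (rep in 1:8) {
    x <- matrix(rnorm(8), 4, 2)
    res <- cluster_groups(x, cluster_columns = FALSE)
    expect_identical(hclust_merge_sets(res$rows$hclust), ward_oracle(x))
  }
})

test_that("a distinct planted profile joins the tree last", {
  cohort <- default_cohort()
  norm <- pqn_normalize(cohort$features)$normalized
  lx <- log10(norm$intensities)
  groups <- cohort$metadata$group
  roles <- cohort$truth$feature_roles
  disc <- names(roles)[startsWith(roles, "discriminant")]
  means <- t(sapply(levels(groups), function(g) colMeans(lx[groups == g, disc])))
  res <- cluster_groups(scale(means), cluster_columns = FALSE)
  hc <- res$rows$hclust
  # acidosis has the strongest planted fingerprint; the final merge
  # separates it from the rest
  final <- hc$merge[nrow(hc$merge), ]
  expect_true(-which(levels(groups) == "acidosis") %in% final)
  # the newick export parses back with the right number of tips
  tree <- ape::read.tree(text = res$rows$newick)
  expect_identical(sort(tree$tip.label), sort(levels(groups)))
})

test_that("clustering is invariant to per-feature affine rescaling after autoscaling", {
  set.seed(34)
  raw <- matrix(rexp(6 * 10), 6, 10)
  rescaled <- sweep(sweep(raw, 2, runif(10, 0.5, 20), "*"), 2, runif(10, -3, 3), "+")
  r1 <- cluster_groups(scale(raw), cluster_columns = FALSE)
  r2 <- cluster_groups(scale(rescaled), cluster_columns = FALSE)
  expect_identical(r1$rows$hclust$merge, r2$rows$hclust$merge)
  expect_error(cluster_groups(matrix(1, 1, 3)), "2 rows")
})

test_that("m/z annotation respects the ppm tolerance exactly", {
  lib <- data.frame(id = c("L1", "L2", "L3"), name = c("x", "y", "z"),
                    mz = c(100.0000, 180.0634, 255.2330))
  feats <- data.frame(feature_id = c("F1", "F2", "F3"),
                      mz = c(100.0000, 100.0010, 180.0637))
  hits <- match_mz(feats, lib, tolerance_ppm = 5)
  expect_identical(hits$feature_id, c("F1", "F3"))
  expect_equal(hits$error_ppm[1], 0)
  # 100.0010 vs 100.0000 is 10 ppm off: no hit at 5 ppm
  expect_false("F2" %in% hits$feature_id)
  expect_error(match_mz(feats, lib, tolerance_ppm = 0), "positive")
  expect_error(match_mz(feats, data.frame(id = c("a", "a"), mz = c(1, 2)),
                        tolerance_ppm = 5), "unique")

  # exhaustive all-pairs oracle on random values
  set.seed(35)
  feats2 <- data.frame(feature_id = paste0("F", 1:50),
                       mz = round(runif(50, 80, 600), 4))
  lib2 <- data.frame(id = paste0("L", 1:80), mz = round(runif(80, 80, 600), 4))
  hits2 <- match_mz(feats2, lib2, tolerance_ppm = 5000)
  oracle <- expand.grid(i = 1:50, j = 1:80)
  oracle$ppm <- (feats2$mz[oracle$i] - lib2$mz[oracle$j]) / lib2$mz[oracle$j] * 1e6
  oracle <- oracle[abs(oracle$ppm) <= 5000, ]
  expect_identical(nrow(hits2), nrow(oracle))
  expect_setequal(paste(hits2$feature_id, hits2$library_id),
                  paste0("F", oracle$i, " L", oracle$j))
})
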