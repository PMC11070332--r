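test_that("argmax assignment picks the dominant response and breaks ties in order", {
  r <- rbind(c(0.7, 0.1, 0.1, 0.05, 0.05))
  colnames(r) <- cod_groups()
  expect_identical(as.character(classify_argmax(r)), "acidosis")
  tie <- rbind(c(0.4, 0.4, 0.2))
  colnames(tie) <- c("x", "y", "z")
  out <- suppressMessages(classify_argmax(tie))
  expect_identical(as.character(out), "x")
  expect_identical(attr(out, "ties"), 1L)
  # brute-force scan oracle on a random matrix
  set.seed(21)
  m <- matrix(runif(200 * 5), 200, 5, dimnames = list(NULL, cod_groups()))
  oracle <- apply(m, 1, function(row) cod_groups()[which.max(row)])
  expect_identical(as.character(classify_argmax(m)), oracle)
  m[1, 1] <- Inf
  expect_error(classify_argmax(m), "finite")
})

test_that("ROC curves satisfy their invariants and the Mann-Whitney identity", {
  # perfectly separated scores
  expect_equal(roc_curve(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE))$auc, 1)
  # six-case hand example with a tie, against the pairwise concordance count
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.2)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  roc <- roc_curve(scores, labels)
  pos <- scores[labels]; neg <- scores[!labels]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  expect_equal(roc$auc, mean(pairs))
  # endpoints and monotonicity
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)
  expect_equal(roc$points$fpr[nrow(roc$points)], 1)
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC agrees with pROC and is near 0.5 for uninformative scores", {
  skip_if_not_installed("pROC")
  set.seed(22)
  scores <- rnorm(400)
  labels <- rep(c(TRUE, FALSE), 200)
  roc <- roc_curve(scores, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              levels = c(FALSE, TRUE),
                                              direction = "<")))
  expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-12)
  expect_lt(abs(roc$auc - 0.5), 0.08)
})

test_that("steepest-segment selection matches an exhaustive oracle", {
  steepest_oracle <- function(roc, tpr_min = 0.3, fpr_max = 0.1) {
    p <- roc$points
    best <- NULL; best_slope <- -Inf
    for (i in 2:nrow(p)) {
      if (!(p$tpr[i] > tpr_min && p$fpr[i] < fpr_max)) next
      dtpr <- p$tpr[i] - p$tpr[i - 1]
      dfpr <- p$fpr[i] - p$fpr[i - 1]
      slope <- if (dfpr == 0) Inf else dtpr / dfpr
      better <- slope > best_slope ||
        (slope == best_slope && (p$fpr[i] < p$fpr[best] ||
          (p$fpr[i] == p$fpr[best] && p$tpr[i] > p$tpr[best])))
      if (better) { best <- i; best_slope <- slope }
    }
    list(threshold = p$threshold[best], tpr = p$tpr[best], fpr = p$fpr[best])
  }
  set.seed(23)
  for (rep in 1:5) {
    scores <- rnorm(200)
    labels <- scores + rnorm(200, sd = 0.7) > 0.5
    roc <- roc_curve(scores, labels)
    expect_identical(steepest_threshold(roc), steepest_oracle(roc))
  }
})

test_that("steepest-segment selection honours the region and slope rules", {
  # hand-built curve: one admissible segment
  roc <- structure(list(points = data.frame(
    threshold = c(Inf, 0.9, 0.6, 0.4),
    tpr = c(0, 0.2, 0.5, 1.0),
    fpr = c(0, 0.05, 0.08, 0.6))), class = "roc_curve")
  sel <- steepest_threshold(roc)
  expect_equal(sel$threshold, 0.6)
  expect_equal(sel$tpr, 0.5)
  # vertical segment beats any finite slope
  roc2 <- structure(list(points = data.frame(
    threshold = c(Inf, 0.9, 0.8, 0.5),
    tpr = c(0, 0.3, 0.6, 0.9),
    fpr = c(0, 0.02, 0.02, 0.05))), class = "roc_curve")
  expect_equal(steepest_threshold(roc2)$threshold, 0.8)
  # nothing in the region: informative error
  roc3 <- structure(list(points = data.frame(
    threshold = c(Inf, 1), tpr = c(0, 1), fpr = c(0, 1))), class = "roc_curve")
  expect_error(steepest_threshold(roc3), "relax the region")
})

test_that("the equal-error threshold balances sensitivity and specificity", {
  set.seed(27)
  scores <- c(rnorm(150, 1.2), rnorm(150))
  labels <- rep(c(TRUE, FALSE), each = 150)
  sel <- equal_error_threshold(roc_curve(scores, labels))
  expect_lt(abs(sel$tpr - (1 - sel$fpr)), 0.05)
  hit <- scores >= sel$threshold
  expect_equal(mean(hit[labels]), sel$tpr)
  expect_equal(mean(hit[!labels]), sel$fpr)
})

test_that("threshold screening categorizes none/unique/multiple correctly", {
  thresholds <- c(a = 0.5, b = 0.5, c = 0.5)
  r <- rbind(low = c(0.1, 0.2, 0.3), one = c(0.6, 0.2, 0.1),
             two = c(0.6, 0.55, 0.1))
  colnames(r) <- names(thresholds)
  res <- threshold_screen(r, thresholds)
  expect_identical(as.character(res$outcome), c("none", "unique", "multiple"))
  expect_identical(res$assigned[[3]], c("a", "b"))
  # brute-force oracle on random responses
  set.seed(24)
  m <- matrix(runif(300), 100, 3, dimnames = list(NULL, names(thresholds)))
  thr <- c(a = 0.3, b = 0.6, c = 0.9)
  res2 <- threshold_screen(m, thr)
  for (i in sample(100, 20)) {
    expect_identical(res2$assigned[[i]], names(thr)[m[i, ] >= thr])
  }
  expect_error(threshold_screen(m, c(bad = 1)), "named")
})

test_that("confusion metrics reproduce the published screening table rows", {
  # acidosis row: counts reconstructed from group size 25 and complement 1045
  acid <- confusion_metrics(16, 5, 9, 1040)
  expect_equal(acid[, c("ppv", "npv", "sensitivity", "specificity", "accuracy")],
               data.frame(ppv = 76.2, npv = 99.1, sensitivity = 64.0,
                          specificity = 99.5, accuracy = 98.7))
  hang <- confusion_metrics(146, 43, 154, 727)
  expect_equal(hang[, c("ppv", "npv", "sensitivity", "specificity", "accuracy")],
               data.frame(ppv = 77.2, npv = 82.5, sensitivity = 48.7,
                          specificity = 94.4, accuracy = 81.6))
  perfect <- confusion_metrics(12, 0, 0, 88)
  expect_true(all(perfect[, c("ppv", "npv", "sensitivity", "specificity",
                              "accuracy")] == 100))
  expect_error(confusion_metrics(-1, 0, 1, 1), "non-negative")
  expect_error(confusion_metrics(0, 1, 0, 1), "tp \\+ fn")
  # zero positive-prediction denominator yields NA, not a fault
  expect_true(is.na(confusion_metrics(0, 0, 5, 95)$ppv))
})

test_that("overall rates reproduce the published prediction totals", {
  expect_equal(overall_rates(c(45, 744, 666, 696, 31), c(75, 1039, 900, 1022, 176)), 68)
  expect_equal(overall_rates(c(14, 217, 219, 236, 9), c(25, 346, 300, 340, 59)), 65)
  expect_equal(overall_rates(c(10, 20), c(10, 20)), 100)
  expect_error(overall_rates(c(11), c(10)), "exceed")
})

test_that("rounding is half-up at the printed precisions", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5)), c(1, 2, 3))
  expect_equal(round_half_up(67.85, 1), 67.9)
  expect_equal(round_half_up(-0.5), -1)
})

test_that("contributing-CoD review reports per-class match fractions", {
  pred <- c("acidosis", "acidosis", "acidosis", "acidosis", "acidosis")
  contrib <- list("acidosis", c("ihd", "acidosis"), "ihd", character(0), "hanging")
  rev <- fp_contributing_review(pred, contrib)
  expect_equal(rev$match_pct[rev$class == "acidosis"], 40)
  none <- fp_contributing_review(c("ihd", "hanging"),
                                 list(character(0), character(0)))
  expect_true(all(none$match_pct == 0))
  expect_match(attr(none, "note"), "n=0 matches")
  # planted match rate is estimated within binomial error
  set.seed(25)
  n <- 600; rate <- 0.3
  pred2 <- sample(cod_groups(), n, replace = TRUE)
  contrib2 <- lapply(seq_len(n), function(i) {
    if (runif(1) < rate) pred2[i] else sample(setdiff(cod_groups(), pred2[i]), 1)
  })
  rev2 <- fp_contributing_review(pred2, contrib2)
  overall <- sum(rev2$n_matching) / sum(rev2$n_false_positive)
  expect_lt(abs(overall - rate), 3 * sqrt(rate * (1 - rate) / n))
})

test_that("raising a threshold trades sensitivity for specificity monotonically", {
  set.seed(26)
  scores <- c(rnorm(100, 1), rnorm(200, 0))
  truth <- rep(c(TRUE, FALSE), c(100, 200))
  grid <- seq(-1, 2, length.out = 15)
  sens <- spec <- numeric(length(grid))
  for (i in seq_along(grid)) {
    hit <- scores >= grid[i]
    sens[i] <- mean(hit[truth])
    spec[i] <- mean(!hit[!truth])
  }
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})
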