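# ---- PLS core ---------------------------------------------------------
# NIPALS PLS2. Each component's X-weight w is the NIPALS fixed point,
# i.e. the dominant eigenvector of X'YY'X, computed via the (small)
# G x G eigenproblem of (Y'X)(X'Y) for numerical stability and
# determinism; with a single response column this reduces to the familiar
# w = X'y / ||X'y||. X and Y are centered internally so the same code
# serves cross-validation folds.
pls_core <- function(X, Y, n_components) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  x_centers <- colMeans(X)
  y_centers <- colMeans(Y)
  Xd <- sweep(X, 2, x_centers)
  Yd <- sweep(Y, 2, y_centers)
  n <- nrow(Xd); k <- ncol(Xd); g <- ncol(Yd)
  W <- P <- matrix(0, k, 0)
  C <- matrix(0, g, 0)
  Tm <- matrix(0, n, 0)
  for (a in seq_len(n_components)) {
    M <- crossprod(Yd, Xd)                  # g x k
    A_small <- tcrossprod(M)                # g x g
    if (max(abs(A_small)) <= .Machine$double.eps * n * k) break
    q <- eigen(A_small, symmetric = TRUE)$vectors[, 1]
    w <- as.numeric(crossprod(M, q))
    wn <- sqrt(sum(w^2))
    if (wn <= sqrt(.Machine$double.eps)) break
    w <- w / wn
    j <- which.max(abs(w))                  # deterministic sign
    w <- sign(w[j]) * w
    t <- as.numeric(Xd %*% w)
    tt <- sum(t^2)
    if (tt <= .Machine$double.eps * n) break
    c <- as.numeric(crossprod(Yd, t)) / tt
    p <- as.numeric(crossprod(Xd, t)) / tt
    Xd <- Xd - tcrossprod(t, p)
    Yd <- Yd - tcrossprod(t, c)
    W <- cbind(W, w); P <- cbind(P, p); C <- cbind(C, c); Tm <- cbind(Tm, t)
  }
  A <- ncol(W)
  B <- if (A > 0) W %*% solve(crossprod(P, W), t(C)) else matrix(0, k, g)
  list(W = W, P = P, C = C, T = Tm, B = B,
       x_centers = x_centers, y_centers = y_centers,
       n_components = A)
}

pls_core_predict <- function(core, X_new) {
  X_new <- rbind(X_new)
  Xd <- sweep(X_new, 2, core$x_centers)
  sweep(Xd %*% core$B, 2, core$y_centers, "+")
}

# Cross-validated PRESS for `a`-component PLS over precomputed folds.
# Returns c(PRESS_a, SS) where SS is the held-out sum of squares about
# the fold-training means (the a = 0 reference).
pls_cv_press <- function(X, Y, folds, a) {
  press <- 0; ss <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    core <- pls_core(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], a)
    pred <- pls_core_predict(core, X[!tr, , drop = FALSE])
    y_val <- rbind(Y[!tr, , drop = FALSE])
    press <- press + sum((y_val - pred)^2)
    ss <- ss + sum(sweep(y_val, 2, colMeans(rbind(Y[tr, , drop = FALSE])))^2)
  }
  c(press = press, ss = ss)
}

#' Fit a PLS or PLS-DA model with cross-validated component selection
#'
#' NIPALS partial least squares against a continuous response (PLS) or a
#' class factor (PLS-DA, via a centered one-hot indicator matrix).
#' Components are added while the incremental per-component Q2 from
#' `n_folds`-fold cross-validation exceeds `q2_min_inc`; a model is
#' "produced" (`valid = TRUE`) when at least one component is retained.
#' This operationalizes the notion of a covariate model being obtained or
#' not during confounder screening.
#'
#' @param X numeric matrix (cases x features), transformed
#'   (centered/scaled); rows aligned with `y`.
#' @param y numeric response vector, or a factor for PLS-DA.
#' @param n_folds number of cross-validation folds (default 7).
#' @param max_components cap on extracted components (default 5).
#' @param q2_min_inc minimum incremental per-component Q2 for retention
#'   (default 0.01).
#' @param cv_seed seed for the fold shuffle.
#' @return An object of class `pls_model` with `valid`, `n_components`,
#'   weights `W`, loadings `P`, y-loadings `C`, scores `T`, regression
#'   coefficients `B`, `r2y`, `q2`, `per_component_q2` and per-feature
#'   `p_corr` (correlation with the first score).
#' @export
fit_pls <- function(X, y, n_folds = 7, max_components = 5,
                    q2_min_inc = 0.01, cv_seed = 1L) {
  X <- as.matrix(X)
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    if (nlevels(y) < 2L) return(invalid_pls_model("single-level class response"))
    Y <- stats::model.matrix(~ 0 + y)
    colnames(Y) <- levels(y)
    strata <- as.character(y)
  } else {
    if (stats::sd(y) == 0) return(invalid_pls_model("constant response"))
    Y <- matrix(as.numeric(y), ncol = 1)
    strata <- rep("all", length(y))
  }
  if (nrow(X) != nrow(Y)) stopf("X and y have different numbers of cases")
  folds <- make_folds(strata, n_folds, seed = cv_seed)

  per_q2 <- numeric(0)
  press_prev <- NULL
  retained <- 0L
  for (a in seq_len(max_components)) {
    cv <- pls_cv_press(X, Y, folds, a)
    if (is.null(press_prev)) press_prev <- cv["ss"]
    q2a <- 1 - cv["press"] / press_prev
    if (!is.finite(q2a) || q2a <= q2_min_inc) break
    per_q2 <- c(per_q2, q2a)
    press_prev <- cv["press"]
    retained <- a
  }
  if (retained == 0L) {
    out <- invalid_pls_model("no component passed the cross-validation rule")
    cv0 <- pls_cv_press(X, Y, folds, 1)
    out$q2 <- unname(1 - cv0["press"] / cv0["ss"])
    return(out)
  }
  core <- pls_core(X, Y, retained)
  cvA <- pls_cv_press(X, Y, folds, core$n_components)
  Yc <- sweep(as.matrix(Y), 2, core$y_centers)
  fitted <- core$T %*% t(core$C)
  p_corr_v <- score_correlations(X, core$T[, 1])
  structure(
    list(valid = TRUE, n_components = core$n_components,
         W = core$W, P = core$P, C = core$C, T = core$T, B = core$B,
         x_centers = core$x_centers, y_centers = core$y_centers,
         r2y = 1 - sum((Yc - fitted)^2) / sum(Yc^2),
         q2 = unname(1 - cvA["press"] / cvA["ss"]),
         per_component_q2 = unname(per_q2),
         p_corr = p_corr_v,
         feature_ids = colnames(X)),
    class = "pls_model"
  )
}

invalid_pls_model <- function(reason) {
  structure(list(valid = FALSE, n_components = 0L, reason = reason,
                 r2y = NA_real_, q2 = NA_real_,
                 per_component_q2 = numeric(0), p_corr = NULL),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  if (!x$valid) {
    cat(sprintf("<pls_model> no model produced (%s)\n", x$reason))
  } else {
    cat(sprintf("<pls_model> %d component(s), R2Y = %.3f, Q2 = %.3f\n",
                x$n_components, x$r2y, x$q2))
  }
  invisible(x)
}

# Pearson correlation of each (already scaled) column with a score vector;
# zero-variance columns get 0 with a warning.
score_correlations <- function(X, t1) {
  sds <- apply(X, 2, stats::sd)
  zero <- sds == 0
  if (any(zero)) warnf("%d zero-variance feature(s): p(corr) set to 0", sum(zero))
  out <- rep(0, ncol(X))
  if (any(!zero)) {
    out[!zero] <- as.numeric(stats::cor(X[, !zero, drop = FALSE], t1))
  }
  names(out) <- colnames(X)
  out
}

#' Correlation loadings p(corr)
#'
#' Pearson correlation between each feature column and the model's first
#' predictive score, the loading representation used for confounder
#' exclusion thresholds.
#'
#' @param model a valid [fit_pls()] (or [fit_oplsda()]) model.
#' @param X the matrix the model was fitted on.
#' @return named numeric vector in \[-1, 1\], one value per feature.
#' @export
p_corr <- function(model, X) {
  t1 <- if (inherits(model, "pls_model")) {
    if (!model$valid) stopf("no model was produced; p(corr) undefined")
    model$T[, 1]
  } else if (inherits(model, "oplsda_model")) {
    model$Tp[, 1]
  } else stopf("unsupported model class")
  score_correlations(as.matrix(X), t1)
}
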