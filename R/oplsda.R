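# ---- OPLS core --------------------------------------------------------
# Orthogonal signal correction for a multi-column response: each
# orthogonal weight is the part of the current component's X-loading that
# is orthogonal to the span of X'Y (the subspace of Y-predictive
# directions), so orthogonal scores are exactly uncorrelated with every Y
# column. After removing n_ortho such components, the predictive block is
# a plain NIPALS PLS2 with n_pred components on the filtered matrix.
opls_core <- function(X, Y, n_ortho, n_pred) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  x_centers <- colMeans(X)
  y_centers <- colMeans(Y)
  Xw <- sweep(X, 2, x_centers)
  Yc <- sweep(Y, 2, y_centers)
  n <- nrow(Xw); k <- ncol(Xw)
  Wo <- Po <- matrix(0, k, 0)
  To <- matrix(0, n, 0)
  for (j in seq_len(n_ortho)) {
    M <- crossprod(Xw, Yc)                        # k x g
    sv <- svd(M)
    basis <- sv$u[, sv$d > max(sv$d[1], 1) * 1e-12, drop = FALSE]
    one <- pls_core(Xw, Yc, 1)                    # leading predictive component
    if (one$n_components < 1L) break
    p <- one$P[, 1]
    wo <- p - basis %*% crossprod(basis, p)
    won <- sqrt(sum(wo^2))
    if (won <= 1e-10) break
    wo <- as.numeric(wo / won)
    jj <- which.max(abs(wo))
    wo <- sign(wo[jj]) * wo
    to <- as.numeric(Xw %*% wo)
    po <- as.numeric(crossprod(Xw, to)) / sum(to^2)
    Xw <- Xw - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  pred <- pls_core(Xw, Yc, n_pred)
  list(Wo = Wo, Po = Po, To = To, pred = pred,
       x_centers = x_centers, y_centers = y_centers,
       n_ortho = ncol(Wo), n_pred = pred$n_components)
}

# Remove orthogonal variation from (centered) new observations, then apply
# the predictive regression.
opls_core_predict <- function(core, X_new) {
  Xf <- opls_filter(core, X_new)
  # pred$x_centers are ~0 (Xw already centered) but apply for exactness
  sweep(sweep(Xf, 2, core$pred$x_centers) %*% core$pred$B,
        2, core$y_centers, "+")
}

opls_filter <- function(core, X_new) {
  Xd <- sweep(rbind(X_new), 2, core$x_centers)
  for (j in seq_len(core$n_ortho)) {
    to <- Xd %*% core$Wo[, j]
    Xd <- Xd - tcrossprod(as.numeric(to), core$Po[, j])
  }
  Xd
}

opls_cv_q2 <- function(X, Y, folds, n_ortho, n_pred) {
  press <- 0; ss <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    core <- opls_core(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], n_ortho, n_pred)
    pred <- opls_core_predict(core, X[!tr, , drop = FALSE])
    y_val <- rbind(Y[!tr, , drop = FALSE])
    press <- press + sum((y_val - pred)^2)
    ss <- ss + sum(sweep(y_val, 2, colMeans(rbind(Y[tr, , drop = FALSE])))^2)
  }
  1 - press / ss
}

#' Fit a multi-class OPLS-DA model
#'
#' Orthogonal partial least squares discriminant analysis of `G` classes:
#' the class membership is one-hot coded, variation in `X` orthogonal to
#' the class response is split off into dedicated orthogonal components,
#' and the predictive components regress the filtered matrix on the
#' centered indicator matrix. Component counts are chosen by
#' `n_folds`-fold cross-validation under one retention rule: starting
#' from `G - 1` predictive components (the minimum spanning all class
#' contrasts), predictive components are added while the cumulative Q2
#' improves by more than `q2_min_inc` (up to `max_pred`); orthogonal
#' components are then added under the same rule (up to `max_ortho`).
#' With heavily imbalanced classes the rare-class contrasts are
#' typically captured only beyond the first `G - 1` components, which is
#' why the predictive count is cross-validated rather than fixed. R2 is
#' the fraction of response sum-of-squares explained by the fit;
#' Q2 = 1 - PRESS/SS from cross-validation.
#'
#' @param X numeric matrix (cases x features), transformed
#'   (centered/scaled).
#' @param groups factor (or coercible) of class labels; every class must
#'   have at least `n_folds` cases.
#' @param n_folds cross-validation folds (default 7); folds are
#'   stratified by class, exhaustive and disjoint.
#' @param n_pred number of predictive components; `NULL` (default)
#'   selects it by cross-validation as described above.
#' @param max_pred cap on predictive components (default 12).
#' @param max_ortho cap on orthogonal components (default 10).
#' @param q2_min_inc minimum Q2 improvement to accept another orthogonal
#'   component (default 0.01).
#' @param cv_seed seed for fold assignment.
#' @return An object of class `oplsda_model` with predictive block
#'   (`Wp`, `Pp`, `Tp`, `C`), orthogonal block (`Wo`, `Po`, `To`),
#'   regression coefficients, `r2`, `q2`, per-feature `vip`, the class
#'   levels, and bookkeeping needed to project new observations.
#' @seealso [predict_responses()], [vip()]
#' @export
fit_oplsda <- function(X, groups, n_folds = 7, n_pred = NULL,
                       max_pred = 12, max_ortho = 10,
                       q2_min_inc = 0.01, cv_seed = 1L) {
  X <- as.matrix(X)
  groups <- factor(groups)
  g <- nlevels(groups)
  if (g < 2L) stopf("need at least 2 classes")
  sizes <- table(groups)
  if (any(sizes < n_folds)) {
    stopf("class(es) with fewer cases than folds (%s); reduce n_folds",
          paste(names(sizes)[sizes < n_folds], collapse = ", "))
  }
  if (nrow(X) != length(groups)) stopf("X rows and group labels differ in length")
  Y <- stats::model.matrix(~ 0 + groups)
  colnames(Y) <- levels(groups)
  folds <- make_folds(as.character(groups), n_folds, seed = cv_seed)

  if (is.null(n_pred)) {
    n_pred <- g - 1L
    q2_pred <- opls_cv_q2(X, Y, folds, 0L, n_pred)
    while (n_pred < max_pred) {
      cand <- opls_cv_q2(X, Y, folds, 0L, n_pred + 1L)
      if (!is.finite(cand) || cand - q2_pred <= q2_min_inc) break
      q2_pred <- cand
      n_pred <- n_pred + 1L
    }
  }

  q2_path <- opls_cv_q2(X, Y, folds, 0L, n_pred)
  n_ortho <- 0L
  while (n_ortho < max_ortho) {
    cand <- opls_cv_q2(X, Y, folds, n_ortho + 1L, n_pred)
    q2_path <- c(q2_path, cand)
    if (!is.finite(cand) || cand - q2_path[n_ortho + 1L] <= q2_min_inc) break
    n_ortho <- n_ortho + 1L
  }
  q2 <- q2_path[n_ortho + 1L]

  core <- opls_core(X, Y, n_ortho, n_pred)
  Yc <- sweep(Y, 2, core$y_centers)
  fitted <- core$pred$T %*% t(core$pred$C)
  r2 <- 1 - sum((Yc - fitted)^2) / sum(Yc^2)

  model <- structure(
    list(classes = levels(groups), n_pred = core$n_pred, n_ortho = core$n_ortho,
         Wp = core$pred$W, Pp = core$pred$P, Tp = core$pred$T, C = core$pred$C,
         Wo = core$Wo, Po = core$Po, To = core$To,
         core = core,
         r2 = r2, q2 = unname(q2), q2_path = unname(q2_path),
         feature_ids = colnames(X), n_cases = nrow(X), n_features = ncol(X),
         n_folds = n_folds, cv_seed = cv_seed),
    class = "oplsda_model"
  )
  model$vip <- vip(model)
  model
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf("<oplsda_model> %d classes, %d predictive + %d orthogonal component(s)\n",
              length(x$classes), x$n_pred, x$n_ortho))
  cat(sprintf("  R2 = %.3f, Q2 = %.3f (%d-fold CV), %d cases x %d features\n",
              x$r2, x$q2, x$n_folds, x$n_cases, x$n_features))
  invisible(x)
}

#' Variable influence on projection (VIP)
#'
#' Per-feature importance over the predictive components,
#' `VIP_k = sqrt( K * sum_a SSY_a w_ak^2 / sum_a SSY_a )` with unit-norm
#' weights and SSY_a the response sum-of-squares explained by component
#' a. By construction the mean of squared VIP values over features is 1,
#' so VIP = 1 marks average influence.
#'
#' @param model a fitted [fit_oplsda()] model.
#' @return named non-negative numeric vector, one value per feature.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "oplsda_model"))
  W <- model$Wp
  k <- nrow(W)
  ssy <- colSums(model$Tp^2) * colSums(model$C^2)
  w2 <- sweep(W^2, 2, colSums(W^2), "/")   # weights are unit-norm already
  v <- sqrt(k * as.numeric(w2 %*% ssy) / sum(ssy))
  stats::setNames(v, model$feature_ids)
}

#' Predict class responses for new observations
#'
#' Projects new cases through the model: orthogonal components are
#' removed, then the predictive regression is applied. Because the
#' responses are fitted to a one-hot indicator matrix, each case's
#' predicted responses sum to exactly 1; the response for class j
#' estimates the (soft) membership of the case in class j.
#'
#' @param model a fitted [fit_oplsda()] model.
#' @param X_new matrix of new observations, transformed with the same
#'   centers/scales as the training matrix; columns must contain the
#'   model's features (matched by name when column names are present).
#' @return matrix (cases x classes) of predicted responses.
#' @export
predict_responses <- function(model, X_new) {
  stopifnot(inherits(model, "oplsda_model"))
  X_new <- rbind(X_new)
  if (!is.null(colnames(X_new)) && !is.null(model$feature_ids)) {
    pos <- match(model$feature_ids, colnames(X_new))
    if (anyNA(pos)) {
      stopf("feature-set mismatch: missing feature(s) %s",
            paste(utils::head(model$feature_ids[is.na(pos)], 5), collapse = ", "))
    }
    X_new <- X_new[, pos, drop = FALSE]
  } else if (ncol(X_new) != model$n_features) {
    stopf("X_new has %d features, model expects %d", ncol(X_new), model$n_features)
  }
  out <- opls_core_predict(model$core, X_new)
  colnames(out) <- model$classes
  rownames(out) <- rownames(X_new)
  out
}

# Score-space projection (predictive + orthogonal) for Hotelling's T2 on
# an OPLS-DA model.
opls_project_scores <- function(model, X_new) {
  Xd <- sweep(rbind(X_new), 2, model$core$x_centers)
  to_all <- matrix(0, nrow(Xd), 0)
  for (j in seq_len(model$n_ortho)) {
    to <- Xd %*% model$Wo[, j]
    to_all <- cbind(to_all, as.numeric(to))
    Xd <- Xd - tcrossprod(as.numeric(to), model$Po[, j])
  }
  # predictive scores via the PLS projection T = X W (P'W)^-1
  R <- model$Wp %*% solve(crossprod(model$Pp, model$Wp))
  tp <- sweep(Xd, 2, model$core$pred$x_centers) %*% R
  cbind(tp, to_all)
}
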