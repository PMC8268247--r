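#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures: variation in X that is
#' orthogonal to the class label is extracted into `n_orth` orthogonal
#' components and removed by deflation before a single predictive component
#' is fit. The label y is coded 0/1 and centered, so predictions are
#' interpretable against a 0.5 threshold.
#'
#' Per orthogonal round on the current X: `w = X'y / (y'y)` normalized;
#' `t = Xw`; `p = X't / (t't)`; `w_o = p - (w'p) w` normalized;
#' `t_o = X w_o`; `p_o = X't_o / (t_o' t_o)`; deflate `X <- X - t_o p_o'`.
#' The predictive component `(w, t, p, c)` is then fit on the filtered X
#' and `R2Y = 1 - ||y - t c||^2 / ||y||^2` (y centered).
#'
#' @param x column-centered (typically unit-variance scaled) numeric matrix,
#'   samples x metabolites.
#' @param y binary 0/1 labels, both classes present.
#' @param n_orth number of orthogonal components (>= 0).
#' @return an object of class `opls_model`: predictive weights `w` (unit
#'   norm), loading `p`, y-loading `c`, scores `t`, orthogonal `w_orth`,
#'   `p_orth`, `t_orth`, plus `y_mean`, `r2y`, `n_orth`.
#' @export
fit_opls_da <- function(x, y, n_orth = 0L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1")
  y_mean <- mean(y)
  yc <- y - y_mean
  m <- ncol(x)
  w_orth <- matrix(0, m, n_orth)
  p_orth <- matrix(0, m, n_orth)
  t_orth <- matrix(0, nrow(x), n_orth)
  xd <- x
  for (k in seq_len(n_orth)) {
    w <- drop(crossprod(xd, yc)) / sum(yc^2)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("degenerate X: zero-norm weight at component ", k)
    w <- w / nw
    tt <- drop(xd %*% w)
    p <- drop(crossprod(xd, tt)) / sum(tt^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) {
      # no y-orthogonal structure left; keep the fitted count honest
      w_orth <- w_orth[, seq_len(k - 1), drop = FALSE]
      p_orth <- p_orth[, seq_len(k - 1), drop = FALSE]
      t_orth <- t_orth[, seq_len(k - 1), drop = FALSE]
      n_orth <- k - 1L
      break
    }
    wo <- wo / nwo
    to <- drop(xd %*% wo)
    po <- drop(crossprod(xd, to)) / sum(to^2)
    xd <- xd - tcrossprod(to, po)
    w_orth[, k] <- wo
    p_orth[, k] <- po
    t_orth[, k] <- to
  }
  w <- drop(crossprod(xd, yc)) / sum(yc^2)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("degenerate X: zero-norm predictive weight")
  w <- w / nw
  tt <- drop(xd %*% w)
  p <- drop(crossprod(xd, tt)) / sum(tt^2)
  cc <- sum(yc * tt) / sum(tt^2)
  r2y <- 1 - sum((yc - tt * cc)^2) / sum(yc^2)
  structure(list(w = w, p = p, c = cc, t = tt,
                 w_orth = w_orth, p_orth = p_orth, t_orth = t_orth,
                 y_mean = y_mean, r2y = r2y, n_orth = as.integer(n_orth),
                 n_metabolites = m),
            class = "opls_model")
}

#' Predict from an OPLS-DA model
#'
#' New samples (scaled with the training centers/scales) are filtered
#' through the orthogonal components in fitting order, then scored on the
#' predictive component: `t = x w`, `y_hat = t c + y_mean`, class
#' `y_hat >= 0.5`. Predicting the training matrix reproduces the training
#' scores.
#'
#' @param object an `opls_model`.
#' @param newdata numeric matrix in training scale.
#' @param ... unused.
#' @return list with `scores`, `y_hat`, `class`.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  xd <- as.matrix(newdata)
  if (ncol(xd) != object$n_metabolites)
    stop("newdata has ", ncol(xd), " metabolites, model expects ",
         object$n_metabolites)
  for (k in seq_len(object$n_orth)) {
    to <- drop(xd %*% object$w_orth[, k])
    xd <- xd - tcrossprod(to, object$p_orth[, k])
  }
  scores <- drop(xd %*% object$w)
  y_hat <- scores * object$c + object$y_mean
  list(scores = scores, y_hat = y_hat, class = as.integer(y_hat >= 0.5))
}

# stratified fold assignment; redraws (seeded) until every fold holds both
# classes, erroring after 100 attempts
make_folds <- function(y, folds, seed) {
  if (folds < 2) stop("folds must be >= 2")
  if (folds > length(y)) stop("more folds than samples")
  set.seed(seed)
  for (attempt in seq_len(100)) {
    assign <- integer(length(y))
    # global label pool keeps fold sizes balanced even when folds == n (LOO)
    pool <- rep_len(seq_len(folds), length(y))
    start <- 0L
    for (cls in unique(y)) {
      idx <- which(y == cls)
      labs <- pool[start + seq_along(idx)]
      assign[idx] <- labs[sample.int(length(labs))]
      start <- start + length(idx)
    }
    ok <- all(vapply(seq_len(folds), function(f) {
      tr <- y[assign != f]
      length(unique(tr)) == 2 && sum(assign == f) > 0
    }, logical(1)))
    if (ok) return(assign)
  }
  stop("could not draw folds with both classes in every training set")
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' `Q2 = 1 - PRESS / SS` from stratified k-fold cross-validation: per
#' training fold the column centers/scales and the OPLS-DA model are refit,
#' held-out samples are scaled with the training parameters and predicted,
#' and PRESS accumulates their squared label error; `SS = ||y - mean(y)||^2`.
#'
#' @param x numeric matrix (any consistent preprocessing stage; scaling is
#'   refit inside each fold).
#' @param y binary 0/1 labels.
#' @param n_orth orthogonal components for each refit.
#' @param folds number of folds (default 7).
#' @param seed fold-assignment seed.
#' @param scale if `FALSE`, x is used as-is per fold (centering only).
#' @return Q2 as a single real (can be negative).
#' @export
q2_cross_validate <- function(x, y, n_orth = 0L, folds = 7L, seed = 1L,
                              scale = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  assign <- make_folds(y, folds, seed)
  press <- 0
  for (f in seq_len(folds)) {
    tr <- assign != f
    te <- !tr
    if (!any(te)) next
    xtr <- x[tr, , drop = FALSE]
    centers <- colMeans(xtr)
    scales <- if (scale) apply(xtr, 2, stats::sd) else rep(1, ncol(xtr))
    scales[scales <= 0 | !is.finite(scales)] <- 1
    xtr <- sweep(sweep(xtr, 2, centers), 2, scales, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2, centers), 2, scales, "/")
    fit <- fit_opls_da(xtr, y[tr], n_orth)
    pred <- predict(fit, xte)
    press <- press + sum((y[te] - pred$y_hat)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Label-permutation check of model significance
#'
#' Recomputes Q2 under `n_perm` random permutations of the labels and
#' reports the permutation p-value `(1 + #{Q2_perm >= Q2_obs}) /
#' (1 + n_perm)`.
#'
#' @inheritParams q2_cross_validate
#' @param n_perm number of permutations (>= 20).
#' @return list of class `opls_fitstats`: `q2`, `q2_permuted`, `perm_p`,
#'   plus `r2y` of the full-data fit.
#' @export
permutation_check <- function(x, y, n_orth = 0L, folds = 7L, n_perm = 100L,
                              seed = 1L, scale = TRUE) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  q2_obs <- q2_cross_validate(x, y, n_orth, folds, seed = derive_seed(seed, "q2"),
                              scale = scale)
  q2_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(derive_seed(seed, "perm-labels", i))
    yp <- sample(y)
    q2_perm[i] <- q2_cross_validate(x, yp, n_orth, folds,
                                    seed = derive_seed(seed, "perm-cv", i),
                                    scale = scale)
  }
  xs <- scale(as.matrix(x))
  fit <- fit_opls_da(xs, y, n_orth)
  structure(list(r2y = fit$r2y, q2 = q2_obs, q2_permuted = q2_perm,
                 perm_p = (1 + sum(q2_perm >= q2_obs)) / (1 + n_perm)),
            class = "opls_fitstats")
}

#' Choose the number of orthogonal components by cross-validated Q2
#'
#' Evaluates Q2 for 0..`max_orth` orthogonal components and returns the
#' count maximizing Q2 subject to a minimum-improvement rule: a larger
#' count is only accepted when it raises Q2 by more than 0.01 (the usual
#' chemometric significance rule for adding a component), and the scan
#' stops as soon as a component drops Q2 by more than 0.01 below the best
#' value seen.
#'
#' @inheritParams q2_cross_validate
#' @param max_orth largest count considered.
#' @return integer in \[0, max_orth\].
#' @export
select_n_orthogonal <- function(x, y, max_orth = 6L, folds = 7L, seed = 1L,
                                scale = TRUE) {
  if (max_orth < 0) stop("max_orth must be >= 0")
  best_q2 <- -Inf
  best_k <- 0L
  for (k in 0:max_orth) {
    q2 <- q2_cross_validate(x, y, k, folds, seed = seed, scale = scale)
    if (k == 0 || q2 > best_q2 + 0.01) { best_q2 <- q2; best_k <- as.integer(k) }
    if (q2 < best_q2 - 0.01) break
  }
  best_k
}
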