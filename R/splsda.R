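# soft-threshold operator: unique minimizer of 0.5||u - v||^2 + lambda||v||_1
soft_threshold <- function(u, lambda) {
  sign(u) * pmax(abs(u) - lambda, 0)
}

# threshold level putting exactly `keep` entries at nonzero: the
# (keep+1)-th largest |u| (0 when keep >= length(u))
keep_lambda <- function(u, keep) {
  a <- sort(abs(u), decreasing = TRUE)
  if (keep >= length(u)) 0 else a[keep + 1]
}

#' Fit a sparse PLS-DA model
#'
#' PLS-DA on a one-column centered dummy of the class label, with LASSO
#' soft-thresholding of each X-loading vector so that every component
#' selects exactly `keep` metabolites. Per component the weight iteration
#' `u <- X'v`, soft-threshold to `keep` nonzeros, normalize, `t = Xu`,
#' `v <- Y't / ||Y't||` runs to convergence; X and Y are then deflated by
#' the regression of each on the component scores.
#'
#' @param x scaled numeric matrix, samples x metabolites.
#' @param y binary 0/1 labels.
#' @param n_components number of components (default 5).
#' @param keep nonzero loadings per component (default 15).
#' @param metabolite_ids optional ids for reporting (default colnames).
#' @param max_iter,tol inner-iteration controls.
#' @return object of class `spls_model`: `loadings_x` (m x H, exactly
#'   `keep` nonzeros per column), `loadings_y`, `scores`, `selected` (ids
#'   per component), `t_ss` (score sum-of-squares per component).
#' @export
fit_spls_da <- function(x, y, n_components = 5L, keep = 15L,
                        metabolite_ids = colnames(x), max_iter = 500L,
                        tol = 1e-9) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  m <- ncol(x)
  if (keep > m) stop("keep must be <= number of metabolites")
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("V", seq_len(m))
  if (keep == m) warning("keep equals the number of metabolites: dense fit")
  yc <- matrix(y - mean(y), ncol = 1)
  xd <- x
  loadings_x <- matrix(0, m, n_components,
                       dimnames = list(metabolite_ids, NULL))
  loadings_y <- numeric(n_components)
  scores <- matrix(0, nrow(x), n_components)
  t_ss <- numeric(n_components)
  selected <- vector("list", n_components)
  cx_list <- vector("list", n_components)
  for (h in seq_len(n_components)) {
    ynorm <- sqrt(sum(yc[, 1]^2))
    if (ynorm < 1e-12) stop("Y residual vanished at component ", h)
    v <- yc[, 1] / ynorm
    u <- rep(0, m)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      u_new <- drop(crossprod(xd, v))
      u_new <- soft_threshold(u_new, keep_lambda(u_new, keep))
      nu <- sqrt(sum(u_new^2))
      if (nu < 1e-12) stop("zero loading at component ", h,
                           " (degenerate X residual)")
      u_new <- u_new / nu
      tt <- drop(xd %*% u_new)
      # one-column Y: the y-side direction is fixed up to sign
      v <- sign(sum(yc[, 1] * tt)) * yc[, 1] / ynorm
      if (sum((u_new - u)^2) < tol) { u <- u_new; converged <- TRUE; break }
      u <- u_new
    }
    if (!converged)
      stop("sPLS-DA inner iteration failed to converge at component ", h)
    tt <- drop(xd %*% u)
    ss <- sum(tt^2)
    cx <- drop(crossprod(xd, tt)) / ss
    cy <- drop(crossprod(yc, tt)) / ss
    xd <- xd - tcrossprod(tt, cx)
    yc <- yc - tt %*% t(cy)
    loadings_x[, h] <- u
    loadings_y[h] <- cy
    scores[, h] <- tt
    t_ss[h] <- ss
    cx_list[[h]] <- cx
    selected[[h]] <- metabolite_ids[u != 0]
  }
  structure(list(n_components = as.integer(n_components),
                 keep = as.integer(keep), loadings_x = loadings_x,
                 loadings_y = loadings_y, scores = scores, t_ss = t_ss,
                 selected = selected, metabolite_ids = metabolite_ids,
                 cx = cx_list, y_mean = mean(y)),
            class = "spls_model")
}

#' Rank metabolites by their sPLS-DA contribution
#'
#' Importance of a metabolite is the maximum over components of
#' `|loading| * (component score sum-of-squares share)`; metabolites
#' selected by no component get importance 0 and rank last. Ties are broken
#' toward the earlier component, then lexicographically by id, so top-k
#' extraction is stable.
#'
#' @param model an `spls_model`.
#' @return data frame `rank`, `metabolite_id`, `importance`, `component`.
#' @export
rank_variables <- function(model) {
  stopifnot(inherits(model, "spls_model"))
  share <- model$t_ss / sum(model$t_ss)
  contrib <- abs(model$loadings_x) %*% diag(share, length(share))
  importance <- apply(contrib, 1, max)
  best_comp <- apply(contrib, 1, which.max)
  best_comp[importance == 0] <- NA_integer_
  o <- order(-importance, best_comp, model$metabolite_ids)
  data.frame(rank = seq_along(o),
             metabolite_id = model$metabolite_ids[o],
             importance = importance[o],
             component = best_comp[o],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-validated classification error rate of sPLS-DA
#'
#' Repeated stratified k-fold cross-validation; each held-out sample is
#' projected into the training model's score space and assigned the class
#' of the nearest class centroid. The error rate is the misclassified
#' fraction averaged over repeats.
#'
#' @inheritParams fit_spls_da
#' @param folds folds per repeat (default 5).
#' @param n_repeats number of repeats (default 10).
#' @param seed master seed.
#' @return error rate in \[0, 1\].
#' @export
cv_error_rate <- function(x, y, n_components = 5L, keep = 15L, folds = 5L,
                          n_repeats = 10L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  errs <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    assign <- make_folds(y, folds, derive_seed(seed, "spls-cv", r))
    wrong <- 0L
    for (f in seq_len(folds)) {
      tr <- assign != f
      te <- !tr
      xtr <- x[tr, , drop = FALSE]
      centers <- colMeans(xtr)
      scales <- apply(xtr, 2, stats::sd)
      scales[scales <= 0 | !is.finite(scales)] <- 1
      xtr <- sweep(sweep(xtr, 2, centers), 2, scales, "/")
      xte <- sweep(sweep(x[te, , drop = FALSE], 2, centers), 2, scales, "/")
      fit <- fit_spls_da(xtr, y[tr], n_components, keep)
      str <- fit$scores
      ste <- project_spls(fit, xte)
      cen1 <- colMeans(str[y[tr] == 1, , drop = FALSE])
      cen0 <- colMeans(str[y[tr] == 0, , drop = FALSE])
      d1 <- rowSums(sweep(ste, 2, cen1)^2)
      d0 <- rowSums(sweep(ste, 2, cen0)^2)
      pred <- as.numeric(d1 < d0)
      wrong <- wrong + sum(pred != y[te])
    }
    errs[r] <- wrong / length(y)
  }
  mean(errs)
}

# project new (training-scaled) samples into the sPLS-DA score space,
# replaying the deflation with training loadings
project_spls <- function(model, x_new) {
  xd <- as.matrix(x_new)
  scores <- matrix(0, nrow(xd), model$n_components)
  for (h in seq_len(model$n_components)) {
    tt <- drop(xd %*% model$loadings_x[, h])
    xd <- xd - tcrossprod(tt, model$cx[[h]])
    scores[, h] <- tt
  }
  scores
}
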