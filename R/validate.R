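#' Stratified discovery/validation split
#'
#' Per class, `floor(fraction * class size)` samples are drawn uniformly at
#' random into the discovery set; the remainder form the validation set.
#' With 146 cases / 272 controls at fraction 0.7 this reproduces the
#' published 102/190 discovery and 44/82 validation arithmetic.
#'
#' @param meta [sample_meta()] restricted to study samples (QC rows are
#'   ignored if present).
#' @param fraction discovery fraction in (0, 1).
#' @param seed draw seed.
#' @return list with character vectors `discovery` and `validation`.
#' @export
stratified_split <- function(meta, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
  st <- meta[meta$role != "qc", , drop = FALSE]
  if (length(unique(st$y)) < 2) stop("both classes must be present")
  set.seed(seed)
  disc <- character(0)
  for (cls in c(1, 0)) {
    ids <- st$sample_id[st$y == cls]
    if (length(ids) < 2) stop("class of size < 2 cannot be split")
    n_disc <- floor(fraction * length(ids))
    disc <- c(disc, sample(ids, n_disc))
  }
  list(discovery = disc, validation = setdiff(st$sample_id, disc))
}

#' ROC curve, AUC with DeLong confidence interval, and the Youden index
#'
#' AUC is computed as the Mann-Whitney U statistic (probability a random
#' case scores above a random control, ties counted 1/2) with an asymptotic
#' 95% confidence interval from the DeLong variance of the case/control
#' placement values. The operating-point curve sweeps thresholds at
#' midpoints between adjacent distinct scores (plus sentinels beyond the
#' range), classifying `score >= threshold` as case. The Youden index
#' `J = max(sensitivity + specificity - 1)` is found by exhaustive scan;
#' ties are broken toward higher sensitivity.
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param labels binary 0/1 labels, both classes present.
#' @param conf_level confidence level for the DeLong interval.
#' @return object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `auc_var`, `auc_ci`, `youden_j`,
#'   `youden_threshold`, `sens_at_j`, `spec_at_j`.
#' @export
roc_analysis <- function(scores, labels, conf_level = 0.95) {
  scores <- as.numeric(scores)
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  n1 <- length(cases)
  n0 <- length(controls)

  # placement values (DeLong): V10_i = P(case_i > control) with ties 1/2
  cmp <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmp)
  v01 <- colMeans(cmp)
  auc <- mean(cmp)
  auc_var <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * sqrt(auc_var)), min(1, auc + z * sqrt(auc_var)))

  su <- sort(unique(scores))
  mids <- if (length(su) > 1) (su[-1] + su[-length(su)]) / 2 else numeric(0)
  thresholds <- c(su[1] - 1, mids, su[length(su)] + 1)
  sens <- vapply(thresholds, function(th) mean(cases >= th), numeric(1))
  spec <- vapply(thresholds, function(th) mean(controls < th), numeric(1))

  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(sens[best])]   # ties -> higher sensitivity

  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc, auc_var = auc_var,
                 auc_ci = ci, conf_level = conf_level,
                 youden_j = j[best], youden_threshold = thresholds[best],
                 sens_at_j = sens[best], spec_at_j = spec[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f), Youden J %.3f at %.3g (sens %.3f, spec %.3f)\n",
              x$auc, 100 * x$conf_level, x$auc_ci[1], x$auc_ci[2],
              x$youden_j, x$youden_threshold, x$sens_at_j, x$spec_at_j))
  invisible(x)
}

# trapezoidal AUC from the operating-point curve; independent of the
# Mann-Whitney path, used for the internal consistency invariant
trapezoid_auc <- function(roc) {
  fpr <- 1 - roc$specificity
  tpr <- roc$sensitivity
  o <- order(fpr, tpr)
  fpr <- c(fpr[o])
  tpr <- c(tpr[o])
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Monte-Carlo (repeated random sub-sampling) validation of OPLS-DA
#'
#' Per iteration: a stratified discovery/validation split is drawn; column
#' centers/scales (and the OPLS-DA model) are fit on the discovery rows
#' only; validation rows are scaled with the discovery parameters,
#' predicted, and scored by AUROC. Iteration seeds derive from the master
#' seed, so any single iteration can be reproduced in isolation.
#'
#' @param x numeric matrix of study samples (rows in `meta` order),
#'   preprocessed up to (but not including) scaling when
#'   `leakage = "refit"`, or fully scaled when `leakage = "global"`.
#' @param y binary 0/1 labels.
#' @param n_iterations number of resampling iterations.
#' @param fraction discovery fraction.
#' @param n_orth orthogonal component count (fixed across iterations).
#' @param seed master seed.
#' @param leakage `"refit"` rescales within each iteration; `"global"`
#'   assumes x is already on its final scale.
#' @return object of class `mccv_result`: `aucs` (full distribution),
#'   `median`, `min`, `max`, `n_iterations`, `fraction`, `seed`.
#' @export
monte_carlo_validation <- function(x, y, n_iterations = 1000L,
                                   fraction = 0.7, n_orth = 1L, seed = 1L,
                                   leakage = c("refit", "global")) {
  leakage <- match.arg(leakage)
  x <- as.matrix(x)
  y <- as.numeric(y)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  meta <- sample_meta(ids, ifelse(y == 1, "case", "control"), y)
  aucs <- numeric(n_iterations)
  retries <- 0L
  for (i in seq_len(n_iterations)) {
    ok <- FALSE
    for (attempt in 0:3) {
      sp <- stratified_split(meta, fraction,
                             seed = derive_seed(seed, "mccv-split",
                                                i * 7L + attempt))
      di <- match(sp$discovery, ids)
      vi <- match(sp$validation, ids)
      stopifnot(length(intersect(di, vi)) == 0)
      res <- try({
        xtr <- x[di, , drop = FALSE]
        if (leakage == "refit") {
          centers <- colMeans(xtr)
          scales <- apply(xtr, 2, stats::sd)
          scales[scales <= 0 | !is.finite(scales)] <- 1
        } else {
          centers <- rep(0, ncol(xtr))
          scales <- rep(1, ncol(xtr))
        }
        xtr <- sweep(sweep(xtr, 2, centers), 2, scales, "/")
        xte <- sweep(sweep(x[vi, , drop = FALSE], 2, centers), 2, scales, "/")
        fit <- fit_opls_da(xtr, y[di], n_orth)
        pred <- predict(fit, xte)
        roc_analysis(pred$scores, y[vi])$auc
      }, silent = TRUE)
      if (!inherits(res, "try-error")) { aucs[i] <- res; ok <- TRUE; break }
      retries <- retries + 1L
    }
    if (!ok) stop("MCCV iteration ", i, " failed after 3 retries: ", res)
  }
  structure(list(aucs = aucs, median = stats::median(aucs),
                 min = min(aucs), max = max(aucs),
                 n_iterations = as.integer(n_iterations),
                 fraction = fraction, n_orth = as.integer(n_orth),
                 seed = as.integer(seed), retries = retries),
            class = "mccv_result")
}

#' @export
print.mccv_result <- function(x, ...) {
  cat(sprintf("MCCV AUROC over %d iterations: median %.3f, min %.3f, max %.3f\n",
              x$n_iterations, x$median, x$min, x$max))
  invisible(x)
}
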