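#' Impute missing values by iterative low-rank (SVD) completion
#'
#' Missing entries are initialized at column means, then repeatedly replaced
#' by the rank-k truncated singular-value reconstruction of the filled
#' matrix until the largest relative change of an imputed entry falls below
#' `tol` or `max_iter` is reached. The rank k is chosen by masking an
#' additional `cv_fraction` of the observed entries, running the completion
#' for k = 1..`max_rank`, and selecting the k with minimum RMSE on the
#' held-out entries. Observed entries are never modified.
#'
#' @param table a [feature_table()]; every metabolite needs >= 2 observed
#'   values.
#' @param max_rank largest rank tried; must be < min(n_samples,
#'   n_metabolites).
#' @param cv_fraction fraction of observed cells held out for rank choice.
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence is flagged, not fatal.
#' @param seed seed for the held-out cell draw.
#' @return list with `table` (complete), `chosen_rank`, `cv_rmse` (per
#'   rank), and `converged`.
#' @export
impute_missing <- function(table, max_rank = 5L, cv_fraction = 0.05,
                           tol = 1e-3, max_iter = 200L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$values
  mask <- table$missing_mask
  all_missing <- which(colSums(!mask) == 0)
  if (length(all_missing))
    stop("metabolite(s) entirely missing: ",
         paste(table$metabolite_ids[all_missing], collapse = ", "))
  few <- which(colSums(!mask) < 2)
  if (length(few))
    stop("metabolite(s) with < 2 observed values: ",
         paste(table$metabolite_ids[few], collapse = ", "))
  if (max_rank >= min(dim(x)))
    stop("max_rank must be < min(n_samples, n_metabolites)")

  if (!any(mask)) {
    return(list(table = table, chosen_rank = 0L, cv_rmse = numeric(0),
                converged = TRUE))
  }

  # rank choice on an extra held-out set of observed cells
  obs <- which(!mask)
  set.seed(seed)
  n_hold <- max(1L, round(cv_fraction * length(obs)))
  hold <- sample(obs, n_hold)
  cv_mask <- mask
  cv_mask[hold] <- TRUE
  cv_rmse <- vapply(seq_len(max_rank), function(k) {
    fit <- svd_complete(x, cv_mask, k, tol, max_iter)
    sqrt(mean((fit$x[hold] - x[hold])^2))
  }, numeric(1))
  chosen <- which.min(cv_rmse)

  fit <- svd_complete(x, mask, chosen, tol, max_iter)
  filled <- fit$x
  # low-rank reconstructions can dip below zero; for intensity-like
  # (strictly positive) metabolites, floor imputed cells at half the
  # smallest observed value so log-type transforms stay well-behaved
  for (j in seq_len(ncol(filled))) {
    obs_j <- x[!mask[, j], j]
    if (all(obs_j > 0)) {
      lo <- min(obs_j) / 2
      mj <- mask[, j]
      filled[mj, j] <- pmax(filled[mj, j], lo)
    }
  }
  out <- table
  out$values <- filled
  out$missing_mask <- matrix(FALSE, nrow(x), ncol(x),
                             dimnames = dimnames(mask))
  list(table = out, chosen_rank = as.integer(chosen), cv_rmse = cv_rmse,
       converged = fit$converged)
}

# iterative truncated-SVD completion; observed cells (mask FALSE) fixed
svd_complete <- function(x, mask, k, tol, max_iter) {
  filled <- x
  cm <- colMeans(x, na.rm = TRUE)
  cm_mat <- matrix(cm, nrow(x), ncol(x), byrow = TRUE)
  filled[mask] <- cm_mat[mask]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- svd(filled, nu = k, nv = k)
    recon <- s$u %*% (s$d[seq_len(k)] * t(s$v))
    delta <- recon[mask] - filled[mask]
    change <- sqrt(sum(delta^2)) / max(sqrt(sum(filled[mask]^2)), 1e-12)
    filled[mask] <- recon[mask]
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("SVD completion did not converge in ", max_iter, " iterations")
  list(x = filled, converged = converged)
}

#' Probabilistic quotient normalization
#'
#' Each sample is divided by its estimated dilution factor: the median over
#' metabolites of the ratio of the sample's intensities to a reference
#' spectrum. The reference is the per-metabolite median over pooled-QC
#' samples (`qc_median`) or over all study samples (`study_median`);
#' `"auto"` uses the QC median when at least 5 QC samples are present. QC
#' samples are normalized by the same rule.
#'
#' @param table complete [feature_table()] of positive intensities.
#' @param meta [sample_meta()] for the table.
#' @param reference `"auto"`, `"qc_median"` or `"study_median"`.
#' @return list with `table` (normalized) and `dilution` (named per-sample
#'   factors).
#' @export
pqn_normalize <- function(table, meta, reference = "auto") {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$missing_mask))
    stop("pqn_normalize requires a complete table (impute first)")
  meta <- align_meta(table, meta)
  qc <- which(meta$role == "qc")
  if (identical(reference, "auto"))
    reference <- if (length(qc) >= 5) "qc_median" else "study_median"
  ref_rows <- switch(reference,
                     qc_median = qc,
                     study_median = which(meta$role != "qc"),
                     stop("unknown PQN reference: ", reference))
  if (length(ref_rows) == 0) stop("no samples available for PQN reference")
  ref <- apply(table$values[ref_rows, , drop = FALSE], 2, stats::median)
  bad <- which(ref <= 0)
  if (length(bad))
    stop("non-positive PQN reference for metabolite(s): ",
         paste(table$metabolite_ids[bad], collapse = ", "))
  quotients <- sweep(table$values, 2, ref, "/")
  dilution <- apply(quotients, 1, stats::median)
  out <- table
  out$values <- table$values / dilution
  list(table = out, dilution = stats::setNames(dilution, table$sample_ids),
       reference = reference, reference_spectrum = ref)
}

#' Generalized logarithm transform
#'
#' Applies `x -> log2((x + sqrt(x^2 + lambda)) / 2)`, a strictly increasing
#' variance-stabilizing transform that is well-defined at zero and tends to
#' `log2(x)` for `x >> sqrt(lambda)`. With `lambda = "auto"` the transform
#' parameter is set to `(m / 10)^2` where m is the smallest positive entry
#' of the table.
#'
#' @param table complete [feature_table()].
#' @param lambda positive real or `"auto"`.
#' @return list with `table` (transformed) and `lambda` (the value used).
#' @export
glog_transform <- function(table, lambda = "auto") {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$missing_mask))
    stop("glog_transform requires a complete table")
  x <- table$values
  if (identical(lambda, "auto")) {
    pos <- x[x > 0]
    if (!length(pos)) stop("no positive entries; cannot set lambda = 'auto'")
    lambda <- (min(pos) / 10)^2
  }
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 ||
      (lambda == 0 && any(x <= 0)))
    stop("lambda must be > 0 (or >= 0 for strictly positive data)")
  out <- table
  out$values <- log2((x + sqrt(x^2 + lambda)) / 2)
  list(table = out, lambda = lambda)
}

#' Center and unit-variance scale each metabolite
#'
#' Columns are shifted to mean zero and divided by their sample SD. The
#' centers and scales are returned so they can be applied unchanged to
#' held-out samples (see `apply_scaling`).
#'
#' @param table complete [feature_table()].
#' @return list with `table` (scaled), `centers`, `scales` (named vectors).
#' @export
autoscale <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$missing_mask)) stop("autoscale requires a complete table")
  centers <- colMeans(table$values)
  scales <- apply(table$values, 2, stats::sd)
  bad <- which(scales <= 0 | !is.finite(scales))
  if (length(bad))
    stop("zero-variance metabolite(s): ",
         paste(table$metabolite_ids[bad], collapse = ", "))
  out <- table
  out$values <- sweep(sweep(table$values, 2, centers), 2, scales, "/")
  list(table = out,
       centers = stats::setNames(centers, table$metabolite_ids),
       scales = stats::setNames(scales, table$metabolite_ids))
}

#' Apply stored centers and scales to a matrix or feature table
#'
#' @param x numeric matrix or [feature_table()] with metabolites matching
#'   the training set.
#' @param centers,scales vectors from [autoscale()].
#' @return object of the same kind as `x`, scaled.
#' @export
apply_scaling <- function(x, centers, scales) {
  if (inherits(x, "feature_table")) {
    x$values <- sweep(sweep(x$values, 2, centers), 2, scales, "/")
    return(x)
  }
  sweep(sweep(x, 2, centers), 2, scales, "/")
}

#' Shapiro-Wilk normality screen per metabolite
#'
#' Advisory only: the statistic and p-value are reported for each
#' metabolite but no filtering is applied downstream.
#'
#' @param table complete [feature_table()] with >= 3 samples.
#' @return data frame with `metabolite_id`, `w_stat`, `p_value`.
#' @export
normality_screen <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (any(table$missing_mask)) stop("normality_screen requires a complete table")
  if (nrow(table$values) < 3)
    stop("normality screen needs >= 3 samples per metabolite")
  res <- apply(table$values, 2, function(col) {
    # shapiro.test caps n at 5000; subsample deterministically if larger
    if (length(col) > 5000) col <- col[seq(1, length(col), length.out = 5000)]
    if (stats::sd(col) == 0) return(c(NA_real_, 0))
    s <- stats::shapiro.test(col)
    c(unname(s$statistic), s$p.value)
  })
  data.frame(metabolite_id = table$metabolite_ids,
             w_stat = res[1, ], p_value = res[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}
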