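#' Fit a QC-sample PCA model of structured experimental variability
#'
#' Pooled-QC injections repeat the same biological material, so their
#' spread is experimental, not biological. A PCA model on the QC rows
#' (column means + first `n_components` right singular vectors of the
#' centered QC matrix) summarizes the structured part of that variability;
#' [remove_qc_variation()] projects it out of every sample.
#'
#' Loadings are ordered by decreasing singular value and sign-fixed so that
#' each component's largest-magnitude element is positive.
#'
#' @param table [feature_table()] preprocessed to the stage at which the
#'   correction will be applied (here: after glog + scaling).
#' @param meta [sample_meta()]; rows with role `qc` define the model.
#' @param n_components number of PCA components (default 2).
#' @return an object of class `qc_model` with `qc_mean` and orthonormal
#'   `loadings` (n_metabolites x n_components).
#' @export
fit_qc_model <- function(table, meta, n_components = 2L) {
  stopifnot(inherits(table, "feature_table"), n_components >= 0)
  qc <- qc_idx(table, meta)
  if (length(qc) < n_components + 1)
    stop("need at least n_components + 1 = ", n_components + 1,
         " QC samples, have ", length(qc))
  xq <- table$values[qc, , drop = FALSE]
  qc_mean <- colMeans(xq)
  if (n_components == 0) {
    loadings <- matrix(numeric(0), ncol(xq), 0)
  } else {
    s <- svd(sweep(xq, 2, qc_mean), nu = 0, nv = n_components)
    loadings <- s$v
    for (k in seq_len(ncol(loadings))) {
      j <- which.max(abs(loadings[, k]))
      if (loadings[j, k] < 0) loadings[, k] <- -loadings[, k]
    }
  }
  rownames(loadings) <- table$metabolite_ids
  structure(list(qc_mean = stats::setNames(qc_mean, table$metabolite_ids),
                 loadings = loadings,
                 n_components = as.integer(n_components),
                 singular_values = if (n_components > 0)
                   s$d[seq_len(n_components)] else numeric(0)),
            class = "qc_model")
}

#' Remove QC-modelled experimental variability by orthogonal projection
#'
#' Every row x (study and QC alike) is replaced by
#' `x - ((x - qc_mean) %*% V) %*% t(V)` where V are the QC-PCA loadings.
#' The operation is an idempotent projector: corrected rows have zero
#' projection onto the loadings subspace after qc_mean centering.
#'
#' @param table [feature_table()] in the same space the model was fit in.
#' @param model a `qc_model` from [fit_qc_model()].
#' @return corrected [feature_table()].
#' @export
remove_qc_variation <- function(table, model) {
  stopifnot(inherits(table, "feature_table"), inherits(model, "qc_model"))
  if (ncol(table$values) != length(model$qc_mean))
    stop("metabolite dimension mismatch: table has ", ncol(table$values),
         ", model has ", length(model$qc_mean))
  if (model$n_components == 0) return(table)
  v <- model$loadings
  centered <- sweep(table$values, 2, model$qc_mean)
  out <- table
  out$values <- table$values - (centered %*% v) %*% t(v)
  out
}
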