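#' Run the full biomarker-discovery pipeline
#'
#' Executes the fixed stage order: imputation, PQN, glog, autoscaling,
#' QC-based orthogonal correction, OPLS-DA fit with cross-validated Q2 and
#' permutation check, Monte-Carlo resampling AUROC validation, sPLS-DA
#' variable selection with ranking and CV error rate, and per-metabolite
#' association statistics for the top-ranked set. Each stage consumes the
#' previous stage's output; every random step uses a seed derived from the
#' master seed keyed by stage name.
#'
#' @param table raw [feature_table()] (may contain missing values).
#' @param meta [sample_meta()] covering every table sample.
#' @param config a [pipeline_config()].
#' @param seed master seed.
#' @param top_k number of top-ranked metabolites taken into the
#'   association stage (default 10).
#' @return a `result_bundle` list: per-stage parameter and output
#'   summaries, the processed feature table, and provenance (seed, config,
#'   stage order).
#' @export
run_pipeline <- function(table, meta, config = pipeline_config(),
                         seed = 1L, top_k = 10L) {
  stopifnot(inherits(table, "feature_table"))
  validate_config(config)
  meta <- align_meta(table, meta)   # errors before any computation
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  imp <- stage("impute", impute_missing(
    table, config$imputation$max_rank, config$imputation$cv_fraction,
    config$imputation$tol, config$imputation$max_iter,
    seed = derive_seed(seed, "impute")))
  pqn <- stage("pqn", pqn_normalize(imp$table, meta, config$pqn$reference))
  gl <- stage("glog", glog_transform(pqn$table, config$glog$lambda))
  sc <- stage("autoscale", autoscale(gl$table))
  norm_screen <- stage("normality", normality_screen(gl$table))

  qc_model <- NULL
  corrected <- sc$table
  n_qc <- sum(meta$role == "qc")
  if (config$qc_correction$n_components > 0 &&
      n_qc > config$qc_correction$n_components) {
    qc_model <- stage("qc_correct", fit_qc_model(
      sc$table, meta, config$qc_correction$n_components))
    corrected <- stage("qc_correct", remove_qc_variation(sc$table, qc_model))
  }

  st <- which(meta$role != "qc")
  x <- corrected$values[st, , drop = FALSE]
  y <- meta$y[st]

  n_orth <- config$opls$n_orthogonal
  if (identical(n_orth, "auto"))
    n_orth <- stage("opls", select_n_orthogonal(
      x, y, config$opls$max_orthogonal, config$opls$cv_folds,
      seed = derive_seed(seed, "n-orth")))
  opls_fit <- stage("opls", fit_opls_da(scale(x), y, n_orth))
  fitstats <- stage("opls", permutation_check(
    x, y, n_orth, config$opls$cv_folds, config$opls$n_permutations,
    seed = derive_seed(seed, "perm")))

  mccv <- stage("validate", monte_carlo_validation(
    x, y, config$validation$n_iterations,
    config$validation$discovery_fraction, n_orth,
    seed = derive_seed(seed, "mccv"),
    leakage = config$validation$leakage))

  spls <- stage("splsda", fit_spls_da(
    scale(x), y, config$splsda$n_components,
    config$splsda$keep_per_component,
    metabolite_ids = corrected$metabolite_ids))
  ranking <- stage("splsda", rank_variables(spls))
  err <- stage("splsda", cv_error_rate(
    x, y, config$splsda$n_components, config$splsda$keep_per_component,
    config$splsda$n_cv_folds, config$splsda$n_cv_repeats,
    seed = derive_seed(seed, "spls-err")))

  top <- utils::head(ranking$metabolite_id[ranking$importance > 0], top_k)
  study_table <- subset_samples(corrected, samples = st)
  assoc <- stage("associate", build_association_table(study_table, y, top))

  structure(list(
    stages = c("impute", "pqn", "glog", "autoscale", "qc_correct",
               "opls", "validate", "splsda", "associate"),
    seed = as.integer(seed),
    config = unclass(config),
    imputation = list(chosen_rank = imp$chosen_rank,
                      cv_rmse = imp$cv_rmse, converged = imp$converged),
    pqn = list(reference = pqn$reference, dilution = pqn$dilution),
    glog = list(lambda = gl$lambda),
    scaling = list(centers = sc$centers, scales = sc$scales),
    normality = norm_screen,
    qc_model = qc_model,
    opls = list(n_orth = as.integer(n_orth), r2y = opls_fit$r2y,
                q2 = fitstats$q2, perm_p = fitstats$perm_p,
                q2_permuted = fitstats$q2_permuted),
    mccv = list(aucs = mccv$aucs, median = mccv$median, min = mccv$min,
                max = mccv$max, n_iterations = mccv$n_iterations),
    splsda = list(selected = spls$selected, ranking = ranking,
                  error_rate = err),
    association = assoc,
    processed_table = corrected,
    labels = stats::setNames(y, corrected$sample_ids[st])
  ), class = "result_bundle")
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("metabodisc result bundle\n")
  cat(sprintf("  OPLS-DA: %d orthogonal component(s), R2Y %.3f, Q2 %.3f, perm p %.3g\n",
              x$opls$n_orth, x$opls$r2y, x$opls$q2, x$opls$perm_p))
  cat(sprintf("  MCCV AUROC (%d iter): median %.3f [%.3f, %.3f]\n",
              x$mccv$n_iterations, x$mccv$median, x$mccv$min, x$mccv$max))
  cat(sprintf("  sPLS-DA error rate: %.3f\n", x$splsda$error_rate))
  cat(sprintf("  top metabolites: %s\n",
              paste(utils::head(x$splsda$ranking$metabolite_id, 5),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize a result bundle to JSON
#'
#' Numerical content round-trips: `read_result_bundle(write_result_bundle(b))`
#' has identical numbers (JSON is written at full double precision).
#'
#' @param bundle a `result_bundle`.
#' @param path output path.
#' @export
write_result_bundle <- function(bundle, path) {
  ser <- unclass(bundle)
  if (!is.null(ser$qc_model)) ser$qc_model <- unclass(ser$qc_model)
  ser$processed_table <- list(
    sample_ids = bundle$processed_table$sample_ids,
    metabolite_ids = bundle$processed_table$metabolite_ids,
    values = bundle$processed_table$values)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Read a serialized result bundle
#' @param path path written by [write_result_bundle()].
#' @return a `result_bundle`-like list (matrices as written, row-major).
#' @export
read_result_bundle <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
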