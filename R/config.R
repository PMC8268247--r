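#' Default pipeline configuration
#'
#' Returns the nested configuration list consumed by [run_pipeline()]. The
#' defaults encode the published workflow settings: a 2-component QC PCA
#' correction, 7-fold cross-validation for Q2, a 70/30 discovery/validation
#' split repeated 1000 times, and sPLS-DA with 5 components keeping 15
#' variables each.
#'
#' @param ... named overrides, e.g. `pipeline_config(validation =
#'   list(n_iterations = 100))`. Overrides are merged per field; unnamed or
#'   unknown fields are an error.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    imputation = list(max_rank = 5L, cv_fraction = 0.05, tol = 1e-3,
                      max_iter = 200L),
    pqn = list(reference = "auto"),   # qc_median when >= 5 QC, else study_median
    glog = list(lambda = "auto"),
    qc_correction = list(n_components = 2L),
    opls = list(n_orthogonal = "auto", max_orthogonal = 6L, cv_folds = 7L,
                n_permutations = 100L),
    validation = list(discovery_fraction = 0.7, n_iterations = 1000L,
                      leakage = "refit"),
    splsda = list(n_components = 5L, keep_per_component = 15L,
                  n_cv_folds = 5L, n_cv_repeats = 10L),
    association = list(alpha = 0.05, adjust = "bonferroni")
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("overrides must be named")
    for (section in names(ov)) {
      if (!section %in% names(cfg))
        stop("unknown config section: ", section)
      sub <- ov[[section]]
      if (!is.list(sub)) stop("override for '", section, "' must be a list")
      for (field in names(sub)) {
        if (!field %in% names(cfg[[section]]))
          stop("unknown config field: ", section, "$", field)
        cfg[[section]][[field]] <- sub[[field]]
      }
    }
  }
  validate_config(cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

validate_config <- function(cfg) {
  frac_in <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x < 1
  posint <- function(x) is.numeric(x) && length(x) == 1 && x >= 1 &&
    x == as.integer(x)
  stopifnot(frac_in(cfg$imputation$cv_fraction),
            frac_in(cfg$validation$discovery_fraction),
            posint(cfg$imputation$max_rank),
            posint(cfg$imputation$max_iter),
            posint(cfg$opls$cv_folds),
            posint(cfg$validation$n_iterations),
            posint(cfg$splsda$n_components),
            posint(cfg$splsda$keep_per_component),
            posint(cfg$splsda$n_cv_folds))
  if (!cfg$pqn$reference %in% c("auto", "qc_median", "study_median"))
    stop("pqn$reference must be auto, qc_median or study_median")
  if (!identical(cfg$glog$lambda, "auto") &&
      !(is.numeric(cfg$glog$lambda) && cfg$glog$lambda > 0))
    stop("glog$lambda must be positive or 'auto'")
  if (cfg$qc_correction$n_components < 0)
    stop("qc_correction$n_components must be >= 0")
  if (!identical(cfg$opls$n_orthogonal, "auto") &&
      !(is.numeric(cfg$opls$n_orthogonal) && cfg$opls$n_orthogonal >= 0))
    stop("opls$n_orthogonal must be >= 0 or 'auto'")
  if (!cfg$validation$leakage %in% c("refit", "global"))
    stop("validation$leakage must be 'refit' or 'global'")
  if (!cfg$association$adjust %in% "bonferroni")
    stop("association$adjust must be 'bonferroni'")
  invisible(cfg)
}

#' Derive a stage-specific seed from a master seed
#'
#' Every random operation in the pipeline consumes a seed derived from the
#' single master seed keyed by stage name (and optionally an iteration
#' index), so any stage can be reproduced in isolation. The derivation is a
#' fixed multiplicative hash modulo 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage character stage key, e.g. `"mccv"`.
#' @param index optional non-negative integer (e.g. resampling iteration).
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, stage, index = 0L) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + as.numeric(index) + 1) %% m
  as.integer(h %% (m - 2) + 1)
}
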