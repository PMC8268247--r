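#' Specify a synthetic case/control/QC cohort
#'
#' The generator emulates a processed untargeted LC-MS feature table at the
#' cohort scale of a nested case-control plasma study: log-normal baseline
#' intensities, block-correlated biological variation, a planted group
#' effect on a small discriminant subset, a low-rank "experimental"
#' nuisance component shared by study and pooled-QC samples, per-sample
#' dilution factors, and a mix of completely-at-random and
#' low-intensity-preferential missing values.
#'
#' Defaults mirror the published cohort: 146 cases, 272 matched controls,
#' 40 pooled-QC injections, 214 identified metabolites, and 10 discriminant
#' metabolites (5 raised and 5 lowered in cases by 1.5 baseline SD).
#'
#' @param n_cases,n_controls,n_qc,n_metabolites cohort dimensions.
#' @param n_discriminant number of metabolites carrying a group effect.
#' @param effect_sizes signed log-scale mean shifts for cases, in units of
#'   the baseline biological SD (`bio_sd`); length `n_discriminant`.
#' @param bio_sd common per-metabolite biological SD on the natural-log
#'   scale.
#' @param dilution_sd SD of the per-sample log dilution factor.
#' @param nuisance_rank,nuisance_sd rank and per-entry SD of the shared
#'   low-rank experimental-variability component.
#' @param noise_sd SD of iid measurement noise on the log scale.
#' @param missing_rate overall fraction of missing entries in \[0, 1).
#' @param mnar_weight fraction of missing entries drawn preferentially from
#'   low intensities (the rest are completely at random).
#' @param block_correlation within-block correlation of biological
#'   variation in \[0, 1); metabolites are grouped in blocks of ~10.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 146L, n_controls = 272L, n_qc = 40L,
                        n_metabolites = 214L, n_discriminant = 10L,
                        effect_sizes = rep(c(1.5, -1.5),
                                           each = ceiling(n_discriminant / 2))[
                                             seq_len(n_discriminant)],
                        bio_sd = 0.3, dilution_sd = 0.3,
                        nuisance_rank = 2L, nuisance_sd = 0.3,
                        noise_sd = 0.08, missing_rate = 0.05,
                        mnar_weight = 0.4, block_correlation = 0.1,
                        seed = 1L) {
  spec <- list(n_cases = as.integer(n_cases),
               n_controls = as.integer(n_controls),
               n_qc = as.integer(n_qc),
               n_metabolites = as.integer(n_metabolites),
               n_discriminant = as.integer(n_discriminant),
               effect_sizes = as.numeric(effect_sizes),
               bio_sd = bio_sd, dilution_sd = dilution_sd,
               nuisance_rank = as.integer(nuisance_rank),
               nuisance_sd = nuisance_sd, noise_sd = noise_sd,
               missing_rate = missing_rate, mnar_weight = mnar_weight,
               block_correlation = block_correlation,
               seed = as.integer(seed))
  if (spec$n_discriminant > spec$n_metabolites)
    stop("n_discriminant must be <= n_metabolites")
  if (length(spec$effect_sizes) != spec$n_discriminant)
    stop("length(effect_sizes) must equal n_discriminant")
  stopifnot(spec$n_cases >= 1, spec$n_controls >= 1, spec$n_qc >= 0,
            spec$bio_sd > 0, spec$dilution_sd >= 0,
            spec$nuisance_rank >= 0, spec$nuisance_sd >= 0,
            spec$noise_sd > 0,
            spec$missing_rate >= 0, spec$missing_rate < 1,
            spec$mnar_weight >= 0, spec$mnar_weight <= 1,
            spec$block_correlation >= 0, spec$block_correlation < 1)
  class(spec) <- c("cohort_spec", "list")
  spec
}

#' Generate a synthetic cohort with known ground truth
#'
#' Log-intensities of study samples are
#' `baseline + biological + effect + nuisance + noise`; raw intensities are
#' `exp(log-intensity) * dilution`. QC samples share the baseline
#' (pooled-mean) profile and the nuisance component but carry no group
#' effect and no biological variation. Missing values are planted after
#' intensities are formed, as a `mnar_weight` : `1 - mnar_weight` mixture
#' of intensity-dependent and completely-at-random positions.
#'
#' @param spec a [cohort_spec()].
#' @return a list with elements `table` (a [feature_table()]), `meta` (a
#'   [sample_meta()] frame: cases, then controls, then QC), and `truth`
#'   (discriminant indices, effect sizes, per-sample dilution factors,
#'   nuisance scores for all rows, and missing positions).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_study <- spec$n_cases + spec$n_controls
  n <- n_study + spec$n_qc
  m <- spec$n_metabolites

  mu <- stats::rnorm(m, mean = log(1e5), sd = 1.0)      # baseline locations
  disc <- sort(sample.int(m, spec$n_discriminant))
  delta <- numeric(m)
  delta[disc] <- spec$effect_sizes * spec$bio_sd

  # block-correlated biological variation, marginal SD = bio_sd
  block <- rep(seq_len(ceiling(m / 10)), each = 10)[seq_len(m)]
  rho <- spec$block_correlation
  g <- matrix(stats::rnorm(n_study * max(block)), n_study, max(block))
  bio <- sqrt(rho) * g[, block, drop = FALSE] +
    sqrt(1 - rho) * matrix(stats::rnorm(n_study * m), n_study, m)
  bio <- spec$bio_sd * bio

  # shared low-rank nuisance, per-entry SD ~ nuisance_sd, all rows
  r <- spec$nuisance_rank
  if (r > 0) {
    scores <- matrix(stats::rnorm(n * r), n, r)
    loadings <- matrix(stats::rnorm(r * m), r, m)
    nuis <- (spec$nuisance_sd / sqrt(r)) * scores %*% loadings
  } else {
    scores <- matrix(numeric(0), n, 0)
    loadings <- matrix(numeric(0), 0, m)
    nuis <- matrix(0, n, m)
  }

  y <- c(rep(1, spec$n_cases), rep(0, spec$n_controls))
  logx <- matrix(mu, n_study, m, byrow = TRUE) + bio +
    outer(y, delta) + nuis[seq_len(n_study), , drop = FALSE] +
    matrix(stats::rnorm(n_study * m, sd = spec$noise_sd), n_study, m)
  if (spec$n_qc > 0) {
    qc_rows <- (n_study + 1):n
    logq <- matrix(mu, spec$n_qc, m, byrow = TRUE) +
      nuis[qc_rows, , drop = FALSE] +
      matrix(stats::rnorm(spec$n_qc * m, sd = spec$noise_sd), spec$n_qc, m)
    logx <- rbind(logx, logq)
  }

  dilution <- exp(stats::rnorm(n, sd = spec$dilution_sd))
  values <- exp(logx) * dilution

  ids <- c(sprintf("case%03d", seq_len(spec$n_cases)),
           sprintf("ctrl%03d", seq_len(spec$n_controls)),
           if (spec$n_qc > 0) sprintf("QC%03d", seq_len(spec$n_qc)))
  met_ids <- sprintf("met%03d", seq_len(m))
  role <- c(rep("case", spec$n_cases), rep("control", spec$n_controls),
            rep("qc", spec$n_qc))

  # missingness: MNAR entries weighted toward low intensity, MCAR uniform
  n_missing <- round(spec$missing_rate * n * m)
  missing_pos <- integer(0)
  if (n_missing > 0) {
    n_mnar <- round(spec$mnar_weight * n_missing)
    pool <- seq_len(n * m)
    if (n_mnar > 0) {
      w <- rank(-values) ^ 4           # strongly favors low intensities
      mnar <- sample(pool, n_mnar, prob = w)
    } else mnar <- integer(0)
    mcar <- sample(setdiff(pool, mnar), n_missing - n_mnar)
    missing_pos <- sort(c(mnar, mcar))
  }
  mask <- matrix(FALSE, n, m)
  mask[missing_pos] <- TRUE
  # keep every metabolite imputable: >= 2 observed values per column
  for (j in which(colSums(!mask) < 2)) {
    keep <- order(values[, j], decreasing = TRUE)[1:2]
    mask[keep, j] <- FALSE
  }
  missing_pos <- which(mask)
  vals <- values
  vals[mask] <- NA_real_

  table <- feature_table(vals, ids, met_ids, mask)
  meta <- sample_meta(ids, role,
                      ifelse(role == "qc", NA_real_, as.numeric(role == "case")),
                      run_order = seq_len(n))
  truth <- list(discriminant_indices = disc,
                discriminant_ids = met_ids[disc],
                effect_sizes = spec$effect_sizes,
                effect_shifts = delta[disc],
                dilution_factors = stats::setNames(dilution, ids),
                nuisance_scores = scores,
                nuisance_loadings = loadings,
                missing_positions = missing_pos,
                baseline_log_mean = mu)
  list(table = table, meta = meta, truth = truth)
}

#' Expected single-metabolite AUC for a planted effect
#'
#' For one discriminant metabolite with a case/control mean shift of
#' `e * bio_sd` on the log scale and per-group variance
#' `bio_sd^2 + nuisance_sd^2 + noise_sd^2`, the two-class AUC under
#' normality is `pnorm(|e| / sqrt(2) / sqrt(1 + v))` with
#' `v = (nuisance_sd^2 + noise_sd^2) / bio_sd^2`. Used to calibrate
#' recovery tests; returns the AUC of the single best metabolite.
#'
#' @param spec a [cohort_spec()].
#' @return expected AUC in \[0.5, 1\].
#' @export
planted_auc <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_discriminant == 0) return(0.5)
  e <- max(abs(spec$effect_sizes))
  v <- (spec$nuisance_sd^2 + spec$noise_sd^2) / spec$bio_sd^2
  stats::pnorm(e / sqrt(2) / sqrt(1 + v))
}
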