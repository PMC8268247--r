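# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (brute force / closed form) and share no
# code with the functions they check.

# single-component PLS1 by NIPALS: w = X'y normalized, t = Xw
oracle_pls1_scores <- function(x, y) {
  yc <- y - mean(y)
  w <- drop(crossprod(x, yc))
  w <- w / sqrt(sum(w^2))
  drop(x %*% w)
}

# AUC by brute-force pair counting, ties 1/2
oracle_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (a in cases) for (b in controls)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cases) * length(controls))
}

# rank-based AUC for large samples (still independent of roc_analysis)
oracle_auc_rank <- function(cases, controls) {
  r <- rank(c(cases, controls))
  n1 <- as.numeric(length(cases)); n0 <- as.numeric(length(controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Youden J by scanning every observed score as a candidate cutoff
oracle_youden <- function(scores, labels) {
  best <- -Inf
  for (th in sort(unique(c(scores, min(scores) - 1)))) {
    sens <- mean(scores[labels == 1] >= th)
    spec <- mean(scores[labels == 0] < th)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Welch two-sample t from first principles
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# logistic log-likelihood for grid-search check of the IRLS slope
oracle_logistic_loglik <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}

# a small, clean cohort for fast structural tests
small_cohort <- function(seed = 11, ...) {
  args <- list(n_cases = 40L, n_controls = 60L, n_qc = 10L,
               n_metabolites = 40L, n_discriminant = 4L,
               effect_sizes = c(1.5, 1.5, -1.5, -1.5),
               missing_rate = 0.03, seed = seed)
  ov <- list(...)
  args[names(ov)] <- ov
  generate_cohort(do.call(cohort_spec, args))
}
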