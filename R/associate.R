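#' Per-metabolite Welch t-tests with Bonferroni adjustment
#'
#' Two-sample Welch (unequal-variance) t-test for each metabolite between
#' cases and controls; p-values are Bonferroni-adjusted over all tested
#' metabolites (`p_adj = min(1, m * p)`). Direction is reported from the
#' sign of the case-minus-control mean difference on the (transformed)
#' scale of the input table.
#'
#' @param table processed [feature_table()] restricted to study samples.
#' @param y binary 0/1 labels in table row order.
#' @return data frame with `metabolite_id`, `mean_case`, `mean_control`,
#'   `t_stat`, `p_raw`, `p_adj`, `direction`, `degenerate`.
#' @export
ttest_bonferroni <- function(table, y) {
  stopifnot(inherits(table, "feature_table"))
  y <- as.numeric(y)
  if (length(y) != nrow(table$values)) stop("length(y) must match table rows")
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("need >= 2 samples per class")
  m <- ncol(table$values)
  rows <- lapply(seq_len(m), function(j) {
    a <- table$values[y == 1, j]
    b <- table$values[y == 0, j]
    degen <- stats::sd(a) == 0 && stats::sd(b) == 0
    if (degen) {
      p <- if (mean(a) == mean(b)) 1 else 0
      tstat <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
    } else {
      ht <- stats::t.test(a, b, var.equal = FALSE)
      p <- ht$p.value
      tstat <- unname(ht$statistic)
    }
    data.frame(metabolite_id = table$metabolite_ids[j],
               mean_case = mean(a), mean_control = mean(b),
               t_stat = tstat, p_raw = p, degenerate = degen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, m * out$p_raw)
  out$direction <- ifelse(out$mean_case >= out$mean_control,
                          "higher_in_cases", "lower_in_cases")
  out[, c("metabolite_id", "mean_case", "mean_control", "t_stat",
          "p_raw", "p_adj", "direction", "degenerate")]
}

#' Single-metabolite binomial logistic regression odds ratio
#'
#' Fits `logit P(y = 1) = b0 + b1 x` by iteratively reweighted least
#' squares (`stats::glm`, binomial logit, tolerance 1e-8, max 50
#' iterations) and reports `OR = exp(b1)` with a 95% Wald confidence
#' interval and two-sided Wald p-value. Because the pipeline feeds
#' unit-variance scaled data, the OR is per 1 SD of the transformed
#' metabolite. Complete or quasi-complete separation is detected and
#' raised as an error rather than reported as a spurious estimate.
#'
#' @param x numeric metabolite vector (transformed scale).
#' @param y binary 0/1 labels.
#' @param conf_level Wald CI level.
#' @return list `or_estimate`, `or_ci` (lo, hi), `p`, `beta`, `se`.
#' @export
logistic_or <- function(x, y, conf_level = 0.95) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  )
  beta <- stats::coef(fit)[["x"]]
  se <- sqrt(stats::vcov(fit)["x", "x"])
  mu <- stats::fitted(fit)
  separated <- !fit$converged || abs(beta) > 20 || se > 50 ||
    (all(mu[y == 1] > 1 - 1e-6) && all(mu[y == 0] < 1e-6))
  if (separated)
    stop("complete or quasi-complete separation: logistic OR not estimable")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or_estimate = exp(beta),
       or_ci = c(exp(beta - z * se), exp(beta + z * se)),
       p = 2 * stats::pnorm(-abs(beta / se)),
       beta = beta, se = se)
}

#' Association table for selected metabolites
#'
#' Joins the Welch-t and logistic-regression summaries for a selected
#' metabolite set, sorted by odds ratio, with `log2_or` included for
#' forest-plot style export. Metabolites whose logistic fit separates are
#' kept with `NA` OR fields and flagged.
#'
#' @param table processed [feature_table()] of study samples.
#' @param y binary 0/1 labels in table row order.
#' @param selected non-empty character vector of metabolite ids.
#' @return data frame, one row per selected metabolite, sorted by OR:
#'   t-test fields plus `or_estimate`, `or_lo`, `or_hi`, `or_p`,
#'   `log2_or`, `separated`.
#' @export
build_association_table <- function(table, y, selected) {
  stopifnot(inherits(table, "feature_table"))
  if (length(selected) == 0) stop("selected metabolite set is empty")
  missing <- setdiff(selected, table$metabolite_ids)
  if (length(missing))
    stop("unknown metabolite id(s): ", paste(missing, collapse = ", "))
  tt <- ttest_bonferroni(table, y)
  tt <- tt[match(selected, tt$metabolite_id), , drop = FALSE]
  lr <- lapply(selected, function(id) {
    j <- match(id, table$metabolite_ids)
    res <- try(logistic_or(table$values[, j], y), silent = TRUE)
    if (inherits(res, "try-error"))
      list(or_estimate = NA_real_, or_ci = c(NA_real_, NA_real_),
           p = NA_real_, separated = TRUE)
    else c(res, list(separated = FALSE))
  })
  out <- cbind(tt,
               data.frame(or_estimate = vapply(lr, `[[`, numeric(1), "or_estimate"),
                          or_lo = vapply(lr, function(z) z$or_ci[1], numeric(1)),
                          or_hi = vapply(lr, function(z) z$or_ci[2], numeric(1)),
                          or_p = vapply(lr, `[[`, numeric(1), "p"),
                          separated = vapply(lr, `[[`, logical(1), "separated")))
  out$log2_or <- log2(out$or_estimate)
  out <- out[order(out$or_estimate), , drop = FALSE]
  rownames(out) <- NULL
  out
}
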