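# a matrix with pure predictive structure plus optional y-orthogonal noise
pure_structure <- function(n = 60, m = 20, seed = 2) {
  set.seed(seed)
  y <- rep(c(1, 0), length.out = n)
  v <- rnorm(m)
  v <- v / sqrt(sum(v^2))
  x <- (y - mean(y)) %o% v
  list(x = x, y = y, v = v)
}

test_that("pure predictive structure yields R2Y = 1 with no orthogonal components", {
  d <- pure_structure()
  fit <- fit_opls_da(d$x, d$y, 0)
  expect_equal(fit$r2y, 1, tolerance = 1e-10)
  expect_equal(sqrt(sum(fit$w^2)), 1, tolerance = 1e-10)
})

test_that("with 0 orthogonal components the predictive scores equal NIPALS PLS1", {
  set.seed(14)
  x <- scale(matrix(rnorm(50 * 15), 50, 15))
  y <- rep(c(1, 0), each = 25)
  fit <- fit_opls_da(x, y, 0)
  t_oracle <- oracle_pls1_scores(x, y)
  cosine <- abs(sum(fit$t * t_oracle)) /
    (sqrt(sum(fit$t^2)) * sqrt(sum(t_oracle^2)))
  expect_equal(cosine, 1, tolerance = 1e-8)
})

test_that("one orthogonal component strips a strong y-orthogonal direction", {
  d <- pure_structure(n = 80, m = 30, seed = 6)
  set.seed(7)
  yc <- d$y - mean(d$y)
  t_o <- rnorm(80)
  t_o <- t_o - sum(t_o * yc) / sum(yc^2) * yc   # exactly orthogonal to y
  p_o <- rnorm(30) + 0.5 * d$v                  # overlapping the predictive v
  x_aug <- d$x + 5 * t_o %o% p_o
  base <- fit_opls_da(d$x, d$y, 0)
  filt <- fit_opls_da(x_aug, d$y, 1)
  expect_equal(cor(filt$t, d$y), cor(base$t, d$y), tolerance = 1e-6)
  # the defining OPLS property: orthogonal scores uncorrelated with y
  expect_lt(abs(sum(filt$t_orth[, 1] * yc)) /
              (sqrt(sum(filt$t_orth[, 1]^2)) * sqrt(sum(yc^2))), 1e-8)
})

test_that("degenerate inputs are rejected", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(fit_opls_da(x, rep(1, 10), 0), "both classes")
  expect_error(fit_opls_da(matrix(0, 10, 2), rep(c(0, 1), 5), 0),
               "degenerate")
})

test_that("training-set prediction reproduces training scores and separable data give AUC 1", {
  co <- small_cohort(missing_rate = 0, dilution_sd = 0,
                     effect_sizes = c(6, 6, -6, -6), noise_sd = 0.05)
  st <- which(co$meta$role != "qc")
  x <- scale(log(co$table$values[st, ]))
  y <- co$meta$y[st]
  fit <- fit_opls_da(x, y, 1)
  pred <- predict(fit, x)
  expect_equal(pred$scores, fit$t, tolerance = 1e-10)
  expect_equal(roc_analysis(pred$scores, y)$auc, 1.0)
  expect_error(predict(fit, x[, 1:5]), "metabolites")
})

test_that("null-cohort validation AUC sits near 0.5", {
  set.seed(33)
  aucs <- vapply(1:20, function(s) {
    x <- matrix(rnorm(126 * 30), 126, 30)
    y <- rep(c(1, 0), length.out = 126)
    fit <- fit_opls_da(scale(x[1:84, ]), y[1:84], 1)
    roc_analysis(predict(fit, scale(x[85:126, ]))$scores, y[85:126])$auc
  }, numeric(1))
  expect_lt(abs(median(aucs) - 0.5), 0.1)
})

test_that("leave-one-out Q2 matches a hand-rolled LOO loop exactly", {
  set.seed(12)
  x <- matrix(rnorm(12 * 6), 12, 6)
  y <- rep(c(1, 0), each = 6)
  q2 <- q2_cross_validate(x, y, n_orth = 0, folds = 12, seed = 5)
  press <- 0
  for (i in 1:12) {
    xtr <- x[-i, ]
    ctr <- colMeans(xtr)
    scl <- apply(xtr, 2, sd)
    xtr <- sweep(sweep(xtr, 2, ctr), 2, scl, "/")
    xte <- sweep(sweep(x[i, , drop = FALSE], 2, ctr), 2, scl, "/")
    fit <- fit_opls_da(xtr, y[-i], 0)
    press <- press + (y[i] - predict(fit, xte)$y_hat)^2
  }
  expect_equal(q2, 1 - press / sum((y - mean(y))^2), tolerance = 1e-12)
})

test_that("Q2 calibrates: high under structure, non-positive under the null", {
  d <- pure_structure(n = 140, m = 25, seed = 10)
  x <- d$x + matrix(rnorm(140 * 25, sd = 0.02), 140, 25)
  expect_gt(q2_cross_validate(x, d$y, 0, folds = 7, seed = 3), 0.9)

  null_q2 <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    x <- matrix(rnorm(80 * 40), 80, 40)
    y <- sample(rep(c(1, 0), each = 40))
    q2_cross_validate(x, y, 1, folds = 7, seed = s)
  }, numeric(1))
  expect_gte(mean(null_q2 <= 0), 0.9)
})

test_that("permutation check flags planted effects and keeps the null honest", {
  co <- small_cohort(missing_rate = 0)
  st <- which(co$meta$role != "qc")
  x <- log(co$table$values[st, ])
  y <- co$meta$y[st]
  fs <- permutation_check(x, y, 1, folds = 7, n_perm = 99, seed = 4)
  expect_lte(fs$perm_p, 0.05)
  expect_gte(fs$r2y, fs$q2)

  fs2 <- permutation_check(x, y, 1, folds = 7, n_perm = 99, seed = 4)
  expect_identical(fs$q2_permuted, fs2$q2_permuted)

  set.seed(9)
  null_p <- vapply(1:10, function(s) {
    x0 <- matrix(rnorm(60 * 20), 60, 20)
    y0 <- rep(c(1, 0), each = 30)
    permutation_check(x0, y0, 0, folds = 5, n_perm = 39, seed = s)$perm_p
  }, numeric(1))
  expect_gte(mean(null_p >= 0.05), 0.9)
})

test_that("orthogonal component count selection reacts to planted structure", {
  d <- pure_structure(n = 100, m = 25, seed = 20)
  x <- d$x + matrix(rnorm(100 * 25, sd = 0.02), 100, 25)
  expect_equal(select_n_orthogonal(x, d$y, max_orth = 3, seed = 2), 0L)
  expect_equal(select_n_orthogonal(x, d$y, max_orth = 0, seed = 2), 0L)

  set.seed(21)
  yc <- d$y - mean(d$y)
  t1 <- rnorm(100); t1 <- t1 - sum(t1 * yc) / sum(yc^2) * yc
  t2 <- rnorm(100); t2 <- t2 - sum(t2 * yc) / sum(yc^2) * yc
  x_aug <- x + 8 * t1 %o% rnorm(25) + 8 * t2 %o% rnorm(25)
  expect_gte(select_n_orthogonal(x_aug, d$y, max_orth = 4, seed = 2), 1L)
})

test_that("deflation shrinks X and label swap only flips score signs", {
  set.seed(25)
  x <- scale(matrix(rnorm(60 * 30), 60, 30) +
               rep(c(1, 0), each = 30) %o% rnorm(30))
  y <- rep(c(1, 0), each = 30)
  # each orthogonal deflation removes positive Frobenius mass
  fit3 <- fit_opls_da(x, y, 3)
  xd <- x
  for (k in seq_len(fit3$n_orth)) {
    xn <- xd - fit3$t_orth[, k] %o% fit3$p_orth[, k]
    expect_lt(sum(xn^2), sum(xd^2))
    xd <- xn
  }
  swap <- fit_opls_da(x, 1 - y, 1)
  orig <- fit_opls_da(x, y, 1)
  expect_equal(swap$t, -orig$t, tolerance = 1e-8)
  expect_equal(swap$r2y, orig$r2y, tolerance = 1e-10)
  # r2y invariant under column permutation
  perm <- sample(30)
  expect_equal(fit_opls_da(x[, perm], y, 1)$r2y, orig$r2y,
               tolerance = 1e-10)
})
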