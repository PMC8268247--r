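test_that("SVD completion recovers an exact rank-1 matrix", {
  set.seed(8)
  a <- runif(40, 1, 3)
  b <- runif(25, 1, 5)
  x <- outer(a, b)
  mask <- matrix(runif(length(x)) < 0.1, nrow(x))
  vals <- x
  vals[mask] <- NA
  ft <- feature_table(vals)
  res <- impute_missing(ft, max_rank = 3, tol = 1e-12, max_iter = 2000,
                        seed = 2)
  expect_equal(res$chosen_rank, 1L)
  expect_lt(max(abs(res$table$values[mask] - x[mask])), 1e-6)
})

test_that("imputation is identity on complete tables and never touches observed cells", {
  co <- small_cohort()
  complete <- small_cohort(missing_rate = 0)
  res0 <- impute_missing(complete$table, max_rank = 2)
  expect_identical(res0$table$values, complete$table$values)

  res <- impute_missing(co$table, max_rank = 2)
  obs <- !co$table$missing_mask
  expect_identical(res$table$values[obs], co$table$values[obs])
  expect_false(any(is.na(res$table$values)))
  expect_false(any(res$table$missing_mask))
})

test_that("imputation errors on unusable columns and ranks", {
  vals <- matrix(runif(12), 4, 3)
  vals[, 2] <- NA
  expect_error(impute_missing(feature_table(vals), 2), "entirely missing")
  vals2 <- matrix(runif(12), 4, 3)
  vals2[1:3, 2] <- NA
  expect_error(impute_missing(feature_table(vals2), 2), "< 2 observed")
  expect_error(impute_missing(feature_table(matrix(runif(12), 4, 3)), 3),
               "max_rank")
})

test_that("noisy rank-3 completion beats the noise floor on held-out cells", {
  set.seed(31)
  n <- 200; m <- 100; sigma <- 0.5
  u <- matrix(rnorm(n * 3), n, 3)
  v <- matrix(rnorm(m * 3), m, 3)
  x <- u %*% t(v) * 2 + matrix(rnorm(n * m, sd = sigma), n, m)
  mask <- matrix(runif(n * m) < 0.15, n)
  vals <- x
  vals[mask] <- NA
  res <- impute_missing(feature_table(vals), max_rank = 5, tol = 1e-6,
                        max_iter = 500, seed = 4)
  rmse <- sqrt(mean((res$table$values[mask] - x[mask])^2))
  expect_lt(rmse, 2 * sigma)
})

test_that("PQN recovers known dilutions and normalizes exactly on toys", {
  # sample equal to 2x the reference -> dilution 2, normalized == reference
  ref <- c(10, 20, 30, 40)
  vals <- rbind(ref, ref, ref, 2 * ref, ref * c(1, 1, 1, 1))
  meta <- sample_meta(paste0("S", 1:5),
                      c("qc", "qc", "qc", "case", "control"),
                      c(NA, NA, NA, 1, 0))
  ft <- feature_table(vals, paste0("S", 1:5))
  res <- pqn_normalize(ft, meta, reference = "qc_median")
  expect_equal(unname(res$dilution[4]), 2.0)
  expect_equal(unname(res$table$values[4, ]), ref)

  # all samples identical -> all dilutions 1, table unchanged
  same <- matrix(rep(ref, 6), 6, byrow = TRUE)
  ft2 <- feature_table(same, paste0("T", 1:6))
  meta2 <- sample_meta(paste0("T", 1:6), rep(c("case", "control"), 3))
  res2 <- pqn_normalize(ft2, meta2, reference = "study_median")
  expect_equal(unname(res2$dilution), rep(1, 6))
  expect_equal(res2$table$values, ft2$values)

  expect_error(pqn_normalize(feature_table(rbind(c(1, 0), c(2, 0)),
                                           c("a", "b")),
                             sample_meta(c("a", "b"), c("case", "control")),
                             "study_median"),
               "non-positive")
})

test_that("scaling one sample by c multiplies its dilution by c, leaving output unchanged", {
  co <- small_cohort(missing_rate = 0)
  base <- pqn_normalize(co$table, co$meta)
  scaled <- co$table
  scaled$values[3, ] <- scaled$values[3, ] * 3.7
  res <- pqn_normalize(scaled, co$meta)
  expect_equal(unname(res$dilution[3] / base$dilution[3]), 3.7,
               tolerance = 1e-12)
  expect_equal(res$table$values[3, ], base$table$values[3, ],
               tolerance = 1e-12)
})

test_that("glog transform matches its algebra and is monotone", {
  ft <- feature_table(matrix(8, 1, 1), "s", "m")
  expect_equal(glog_transform(ft, lambda = 1e-300)$table$values[1, 1], 3,
               tolerance = 1e-9)
  ft0 <- feature_table(matrix(0, 1, 1), "s", "m")
  expect_equal(glog_transform(ft0, lambda = 1)$table$values[1, 1], -1)

  x <- sort(c(0, 10^runif(50, -3, 5)))
  for (lam in c(0.01, 1, 100)) {
    g <- glog_transform(feature_table(matrix(x, 1), "s"), lam)$table$values
    expect_true(all(diff(drop(g)) > 0))
  }
  expect_error(glog_transform(ft, lambda = -1), "lambda")

  # auto rule: lambda = (min positive entry / 10)^2
  ft2 <- feature_table(matrix(c(4, 9, 25, 100), 2), c("a", "b"))
  expect_equal(glog_transform(ft2, "auto")$lambda, (4 / 10)^2)
})

test_that("autoscale yields exact zero-mean unit-SD columns and is replayable", {
  co <- small_cohort(missing_rate = 0)
  res <- autoscale(co$table)
  expect_lt(max(abs(colMeans(res$table$values))), 1e-12)
  expect_lt(max(abs(apply(res$table$values, 2, sd) - 1)), 1e-12)
  replay <- apply_scaling(co$table, res$centers, res$scales)
  expect_equal(replay$values, res$table$values)

  const <- feature_table(cbind(rnorm(5), rep(2, 5)), paste0("s", 1:5),
                         c("ok", "flat"))
  expect_error(autoscale(const), "flat")
})

test_that("impute -> pqn -> glog chain is equivariant under sample relabeling", {
  co <- small_cohort(missing_rate = 0)
  perm <- sample(seq_len(nrow(co$table$values)))
  tab_p <- subset_samples(co$table, perm)
  meta_p <- co$meta[perm, ]
  a <- glog_transform(pqn_normalize(co$table, co$meta)$table, 1)$table
  b <- glog_transform(pqn_normalize(tab_p, meta_p)$table, 1)$table
  expect_equal(b$values, a$values[perm, ])
})

test_that("normality screen separates normal from exponential columns", {
  set.seed(77)
  pn <- replicate(100, normality_screen(
    feature_table(matrix(rnorm(500), 500), paste0("s", 1:500)))$p_value)
  expect_gte(mean(pn > 0.01), 0.95)
  pe <- replicate(100, normality_screen(
    feature_table(matrix(rexp(500), 500), paste0("s", 1:500)))$p_value)
  expect_gte(mean(pe < 0.01), 0.95)
  expect_error(normality_screen(feature_table(matrix(1:2, 2), c("a", "b"))),
               ">= 3")
})
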