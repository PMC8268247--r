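# builds a table whose QC rows live exactly in a 2-D affine plane
exact_plane_cohort <- function(n_qc = 8, m = 12, seed = 5) {
  set.seed(seed)
  center <- rnorm(m, 10)
  basis <- qr.Q(qr(matrix(rnorm(m * 2), m, 2)))
  sc <- matrix(rnorm(n_qc * 2, sd = 2), n_qc, 2)
  qc <- sweep(sc %*% t(basis), 2, center, "+")
  study <- matrix(rnorm(6 * m, mean = 10), 6, m)
  vals <- rbind(study, qc)
  ids <- c(paste0("s", 1:6), paste0("q", seq_len(n_qc)))
  meta <- sample_meta(ids, c(rep(c("case", "control"), 3), rep("qc", n_qc)))
  list(table = feature_table(vals, ids), meta = meta, basis = basis)
}

test_that("QC PCA reconstructs an exact rank-2 QC cloud", {
  d <- exact_plane_cohort()
  model <- fit_qc_model(d$table, d$meta, 2)
  expect_equal(crossprod(model$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  qc <- d$table$values[7:14, ]
  centered <- sweep(qc, 2, model$qc_mean)
  recon <- centered %*% model$loadings %*% t(model$loadings)
  expect_lt(max(abs(recon - centered)), 1e-8)
  # sign fix: largest-magnitude element of each loading is positive
  for (k in 1:2)
    expect_gt(model$loadings[which.max(abs(model$loadings[, k])), k], 0)
})

test_that("zero components means identity correction; few QC samples error", {
  d <- exact_plane_cohort()
  m0 <- fit_qc_model(d$table, d$meta, 0)
  expect_equal(ncol(m0$loadings), 0)
  expect_equal(remove_qc_variation(d$table, m0)$values, d$table$values)
  expect_error(fit_qc_model(d$table, d$meta, 8), "QC samples")
})

test_that("the correction is an idempotent projector", {
  d <- exact_plane_cohort(n_qc = 10, m = 20, seed = 9)
  model <- fit_qc_model(d$table, d$meta, 2)
  once <- remove_qc_variation(d$table, model)
  twice <- remove_qc_variation(once, model)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
  proj <- sweep(once$values, 2, model$qc_mean) %*% model$loadings
  expect_lt(max(abs(proj)), 1e-10)
  bad <- feature_table(matrix(rnorm(10), 2, 5), c("x", "y"))
  expect_error(remove_qc_variation(bad, model), "dimension mismatch")
})

test_that("removed variance obeys Pythagoras", {
  d <- exact_plane_cohort(n_qc = 10, m = 20, seed = 3)
  model <- fit_qc_model(d$table, d$meta, 2)
  corrected <- remove_qc_variation(d$table, model)
  centered <- sweep(d$table$values, 2, model$qc_mean)
  cc <- sweep(corrected$values, 2, model$qc_mean)
  removed <- centered %*% model$loadings
  expect_equal(sum(centered^2), sum(cc^2) + sum(removed^2),
               tolerance = 1e-8)
  expect_lte(sum(cc^2), sum(centered^2))
})

test_that("planted rank-2 nuisance is found and neutralized on synthetic cohorts", {
  stats <- sapply(1:5, function(s) {
    co <- generate_cohort(cohort_spec(seed = 16 + s, missing_rate = 0))
    pq <- pqn_normalize(co$table, co$meta)
    sc <- autoscale(glog_transform(pq$table)$table)
    model <- fit_qc_model(sc$table, co$meta, 2)

    # true nuisance directions mapped into the scaled space (log2 / scales)
    lt <- qr.Q(qr(t(co$truth$nuisance_loadings) / (log(2) * sc$scales)))
    sv <- svd(crossprod(model$loadings, lt))$d
    angle <- acos(min(pmin(sv, 1))) * 180 / pi

    corrected <- remove_qc_variation(sc$table, model)
    st <- which(co$meta$role != "qc")
    # per-metabolite correlation with the true nuisance scores, before/after
    mean_cor <- function(vals) mean(vapply(1:2, function(k)
      mean(abs(cor(vals[st, ], co$truth$nuisance_scores[st, k]))),
      numeric(1)))
    reduction <- mean_cor(sc$table$values) / mean_cor(corrected$values)

    # case/control separation on discriminant metabolites is preserved
    y <- co$meta$y[st]
    before <- sc$table$values[st, co$truth$discriminant_indices]
    after <- corrected$values[st, co$truth$discriminant_indices]
    d_before <- colMeans(before[y == 1, ]) - colMeans(before[y == 0, ])
    d_after <- colMeans(after[y == 1, ]) - colMeans(after[y == 0, ])
    c(angle = angle, reduction = reduction,
      pres = median(abs(d_after - d_before) / abs(d_before)))
  })
  expect_lt(median(stats["angle", ]), 10)
  expect_gt(median(stats["reduction", ]), 4)   # nuisance cut several-fold
  expect_lt(median(stats["pres", ]), 0.10)
})

test_that("correction does not hurt downstream discrimination when nuisance is label-free", {
  deltas <- vapply(1:20, function(s) {
    co <- generate_cohort(cohort_spec(n_cases = 40, n_controls = 60,
                                      n_qc = 12, n_metabolites = 60,
                                      nuisance_sd = 0.4, missing_rate = 0,
                                      seed = 100 + s))
    pq <- pqn_normalize(co$table, co$meta)
    sc <- autoscale(glog_transform(pq$table)$table)
    st <- which(co$meta$role != "qc")
    y <- co$meta$y[st]
    model <- fit_qc_model(sc$table, co$meta, 2)
    corrected <- remove_qc_variation(sc$table, model)
    auc_of <- function(x) {
      sp <- stratified_split(co$meta, 0.7, seed = s)
      di <- match(sp$discovery, co$meta$sample_id[st])
      vi <- match(sp$validation, co$meta$sample_id[st])
      ctr <- colMeans(x[di, ])
      scl <- apply(x[di, ], 2, sd)
      xtr <- sweep(sweep(x[di, ], 2, ctr), 2, scl, "/")
      xte <- sweep(sweep(x[vi, ], 2, ctr), 2, scl, "/")
      fit <- fit_opls_da(xtr, y[di], 1)
      roc_analysis(predict(fit, xte)$scores, y[vi])$auc
    }
    auc_of(corrected$values[st, ]) - auc_of(sc$table$values[st, ])
  }, numeric(1))
  expect_gte(median(deltas), 0)
})
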