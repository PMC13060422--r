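# patient_icc = 0 here: patient random intercepts are shared across bins, so
# they do not average out of per-bin batch coefficients and would blur the
# offset-recovery calibration, which targets the correction itself
sim_batch <- function(seed = 1, offsets = c(instA = 0.5, instB = -0.5,
                                            instC = 0)) {
  simulate_rmds_matrix(n_patients_per_group = 15, n_bins = 300,
                       effect_bins = 1:30, effect_size = 1,
                       institute_offsets = offsets, patient_icc = 0,
                       seed = seed)
}

test_that("batch coefficients are near zero when no batch effect is planted", {
  sim <- simulate_rmds_matrix(n_patients_per_group = 15, n_bins = 300,
                              effect_bins = 1:30, effect_size = 1,
                              patient_icc = 0.2, seed = 2)
  cm <- fit_correction(sim$values, sim$metadata,
                       batch_factors = "institute")
  expect_lt(max(abs(rowMeans(cm$beta_batch))), 0.1)
})

test_that("planted institute offsets are recovered and removed", {
  sim <- sim_batch(seed = 4)
  cm <- fit_correction(sim$values, sim$metadata,
                       batch_factors = "institute")
  expect_equal(mean(cm$beta_batch["institute.instA", ]), 0.5,
               tolerance = 0.05)
  expect_equal(mean(cm$beta_batch["institute.instB", ]), -0.5,
               tolerance = 0.05)
  corr <- apply_correction(sim$values, sim$metadata, cm)
  for (inst in c("instA", "instB")) {
    resid <- mean(corr[sim$metadata$institute == inst, ]) - mean(corr)
    expect_lt(abs(resid), 0.05)
  }
})

test_that("a batch factor confounded with response is a rank error", {
  sim <- sim_batch(seed = 5)
  md <- data.table::copy(sim$metadata)
  md[, site := response]  # institute identical to the response grouping
  expect_error(fit_correction(sim$values, md, batch_factors = "site"),
               "rank deficient")
})

test_that("frozen coefficients transfer to held-out samples without leakage", {
  sim <- sim_batch(seed = 6)
  md <- sim$metadata
  holdout <- md$patient_id %in% unique(md$patient_id)[1:6]
  cm <- fit_correction(sim$values[!holdout, ], md[!holdout],
                       batch_factors = "institute")
  corr_te <- apply_correction(sim$values[holdout, ], md[holdout], cm)
  # planted offset removed on held-out samples from seen institutes
  for (inst in c("instA", "instB")) {
    sel <- md$institute[holdout] == inst
    if (!any(sel)) next
    resid <- mean(corr_te[sel, 31:300]) - mean(corr_te[, 31:300])
    expect_lt(abs(resid), 0.15)
  }
  # no leakage: perturbing held-out values does not change the model, and
  # the correction applied is the same linear map
  pert <- sim$values[holdout, ] + 100
  corr_pert <- apply_correction(pert, md[holdout], cm)
  expect_equal(corr_pert - corr_te, matrix(100, nrow(corr_te),
                                           ncol(corr_te)),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("unseen factor levels get the grand-mean correction with warning", {
  sim <- sim_batch(seed = 7)
  md <- sim$metadata
  cm <- fit_correction(sim$values, md, batch_factors = "institute")
  md_new <- data.table::copy(md[1:3])
  md_new[, institute := "instNEW"]
  expect_warning(out <- apply_correction(sim$values[1:3, ], md_new, cm),
                 "unseen")
  expect_identical(out, sim$values[1:3, ])  # zero encoding: nothing subtracted
})

test_that("applying to the fit set equals classical fit-and-subtract", {
  sim <- sim_batch(seed = 8)
  cm <- fit_correction(sim$values, sim$metadata,
                       batch_factors = "institute")
  corr <- apply_correction(sim$values, sim$metadata, cm)
  skip_if_not_installed("limma")
  ref <- t(limma::removeBatchEffect(
    t(sim$values), batch = sim$metadata$institute,
    design = stats::model.matrix(~response, data = sim$metadata)))
  expect_equal(unname(corr), unname(ref), tolerance = 1e-8)
})

test_that("standardization is idempotent and drops constant bins", {
  sim <- sim_batch(seed = 9)
  v <- sim$values
  v[, 1] <- 3  # constant bin
  expect_message(s1 <- standardize_bins(v), "dropped")
  expect_equal(ncol(s1), ncol(v) - 1L)
  expect_equal(max(abs(colMeans(s1))), 0, tolerance = 1e-10)
  expect_equal(max(abs(sqrt(colMeans(s1^2)) - 1)), 0, tolerance = 1e-10)
  s2 <- standardize_bins(s1)
  expect_equal(s2, s1, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("truncated SVD matches an eigen oracle and reconstructs rank", {
  set.seed(10)
  # rank-2 matrix
  a <- matrix(rnorm(40), 20, 2) %*% matrix(rnorm(16), 2, 8)
  emb <- svd_reduce(a, 2)
  recon <- emb$scores %*% t(emb$v)
  expect_equal(unname(recon), unname(a), tolerance = 1e-8)
  # full rank: explained variance sums to 1
  b <- matrix(rnorm(50 * 8), 50, 8)
  emb_b <- svd_reduce(b, 8)
  expect_equal(sum(emb_b$explained_variance), 1, tolerance = 1e-8)
  # oracle: eigenvalues of the Gram matrix
  m <- matrix(rnorm(50 * 200), 50, 200)
  emb_m <- svd_reduce(m, 6)
  ev <- eigen(m %*% t(m), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(emb_m$explained_variance, ev / sum(ev), tolerance = 1e-8)
  # scores orthogonal
  g <- crossprod(emb_m$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-6 * max(diag(g)))
  # determinism incl. sign canonicalization
  expect_identical(svd_reduce(m, 6)$scores, emb_m$scores)
  expect_error(svd_reduce(m, 51), "n_components")
})

test_that("silhouette separates constructed clusters and is null-calibrated", {
  set.seed(11)
  tight <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
                 matrix(rnorm(40, 10, 0.1), 20, 2))
  labels <- rep(c("a", "b"), each = 20)
  s <- silhouette_separation(tight, labels)
  expect_gt(s$mean, 0.9)
  skip_if_not_installed("cluster")
  ref <- cluster::silhouette(as.integer(factor(labels)), dist(tight))
  expect_equal(s$scores, unname(ref[, "sil_width"]), tolerance = 1e-10)
  # permuted labels: mean near zero
  perm_means <- replicate(20, {
    silhouette_separation(tight, sample(labels))$mean
  })
  expect_lt(abs(mean(perm_means)), 0.1)
  # identical points -> 0 by convention
  same <- matrix(1, 4, 2)
  expect_equal(silhouette_separation(same, c("a", "a", "b", "b"))$mean, 0)
  expect_warning(silhouette_separation(tight[1:3, ], c("a", "a", "b")),
                 "singleton")
})
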