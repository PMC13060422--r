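meta_grid <- function(npat = 40, ntp = 3) {
  md <- data.table::data.table(
    patient_id = rep(sprintf("P%03d", 1:npat), each = ntp),
    timepoint = rep(c("Screen", "Day0", "AdjWk1")[1:ntp], npat))
  md[, sample_id := paste(patient_id, timepoint, sep = "_")]
  md[, response := rep(rep(c("Responder", "Non-Responder"),
                           each = npat / 2), each = ntp)]
  md
}

test_that("block correlation recovers a planted ICC and a null gives ~0", {
  set.seed(30)
  md <- meta_grid(40, 3)
  icc <- 0.5
  u <- rnorm(40, 0, sqrt(icc))
  y <- matrix(rnorm(120 * 500, 0, sqrt(1 - icc)), 120, 500) +
    u[rep(1:40, each = 3)]
  rownames(y) <- md$sample_id
  expect_lt(abs(as.numeric(estimate_block_correlation(y, md)) - 0.5), 0.1)
  y0 <- matrix(rnorm(120 * 500), 120, 500)
  rownames(y0) <- md$sample_id
  expect_lt(abs(as.numeric(estimate_block_correlation(y0, md))), 0.05)
})

test_that("a single timepoint per patient yields rho 0 with a warning", {
  md <- meta_grid(20, 1)
  y <- matrix(rnorm(20 * 50), 20, 50, dimnames = list(md$sample_id, NULL))
  expect_warning(rho <- estimate_block_correlation(y, md), "repeated")
  expect_equal(as.numeric(rho), 0)
})

test_that("rho = 0 reduces the GLS fit to OLS exactly", {
  sim <- simulate_rmds_matrix(n_patients_per_group = 10, n_bins = 100,
                              effect_bins = 1:10, effect_size = 1,
                              patient_icc = 0, seed = 31)
  tab_gls <- fit_differential(sim$values, sim$metadata, rho = 0,
                              q_method = "bh")
  # OLS oracle per bin via lm
  md <- sim$metadata
  resp <- as.numeric(md$response == "Responder")
  for (b in c(1, 5, 50)) {
    fit <- lm(sim$values[, b] ~ resp)
    row <- tab_gls[tab_gls$bin == paste0("bin_", b)]
    expect_equal(row$effect, unname(coef(fit)[2]), tolerance = 1e-10)
  }
})

test_that("moderated statistics agree with the limma oracle", {
  skip_if_not_installed("limma")
  sim <- simulate_rmds_matrix(n_patients_per_group = 12, n_bins = 400,
                              effect_bins = 1:40, effect_size = 0.8,
                              patient_icc = 0.4, seed = 32)
  md <- sim$metadata
  rho <- as.numeric(estimate_block_correlation(sim$values, md))
  tab <- fit_differential(sim$values, md, rho = rho, q_method = "bh")

  design <- stats::model.matrix(~ response, data = md)
  # limma codes Responder as the non-reference level alphabetically:
  # Non-Responder < Responder so coefficient 2 is Responder - Non-Responder
  fit <- limma::lmFit(t(sim$values), design, block = md$patient_id,
                      correlation = rho)
  fit <- limma::eBayes(fit)
  ord <- match(tab$bin, rownames(fit$coefficients))
  expect_equal(tab$effect, unname(fit$coefficients[ord, 2]),
               tolerance = 1e-6)
  expect_equal(tab$t, unname(fit$t[ord, 2]), tolerance = 5e-3)
  expect_equal(tab$p, unname(fit$p.value[ord, 2]), tolerance = 5e-3)
  expect_equal(attr(tab, "df_prior"), fit$df.prior, tolerance = 0.05)
})

test_that("planted effects are recovered with correct sign; null is clean", {
  sim <- simulate_rmds_matrix(n_patients_per_group = 20, n_bins = 2000,
                              effect_bins = 1:100, effect_size = 1,
                              patient_icc = 0.4, seed = 33)
  tab <- fit_differential(sim$values, sim$metadata,
                          covariates = c("age", "gender"))
  sig <- tab$bin[!is.na(tab$q) & tab$q < 0.1]
  eff <- paste0("bin_", 1:100)
  expect_gte(mean(eff %in% sig), 0.8)
  # cluster2 pattern raises NR, so responder - non-responder is negative
  est <- tab$effect[match(eff, tab$bin)]
  expect_gt(mean(est < 0), 0.99)
  # q monotone in p
  ord <- order(tab$p)
  expect_true(!is.unsorted(tab$q[ord], na.rm = TRUE))
  expect_true(all(tab$q <= 1, na.rm = TRUE))
})

test_that("forcing d0 to infinity reproduces a pooled-variance z-test", {
  sim <- simulate_rmds_matrix(n_patients_per_group = 8, n_bins = 300,
                              effect_bins = integer(0), patient_icc = 0,
                              seed = 34)
  md <- sim$metadata
  tab <- fit_differential(sim$values, md, rho = 0, prior_df = Inf,
                          q_method = "bh")
  expect_true(is.infinite(attr(tab, "df_prior")))
  # hand-built pooled-variance z-test: common variance = the moment-based
  # s0^2 of the log-residual-variance distribution, normal reference
  resp <- as.numeric(md$response == "Responder")
  X <- cbind(1, resp)
  qx <- qr(X)
  beta <- qr.coef(qx, sim$values)[2, ]
  df <- nrow(X) - 2
  s2 <- colSums(qr.resid(qx, sim$values)^2) / df
  s2_pooled <- exp(mean(log(s2)) - digamma(df / 2) + log(df / 2))
  unit <- chol2inv(qr.R(qx))[2, 2]
  z <- beta / sqrt(unit * s2_pooled)
  ord <- match(paste0("bin_", 1:300), tab$bin)
  expect_equal(tab$t[ord], unname(z), tolerance = 1e-6)
  expect_equal(tab$p[ord], unname(2 * pnorm(-abs(z))), tolerance = 1e-6)
})

test_that("BH q-values match the hand computation and Storey is calibrated", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(fdr_qvalues(p, "bh"), c(0.004, 0.02, 4 * 0.02 / 3, 0.8),
               tolerance = 1e-12)
  expect_equal(fdr_qvalues(rep(1, 5), "bh"), rep(1, 5))
  expect_equal(fdr_qvalues(rep(1, 5), "storey"), rep(1, 5))
  set.seed(35)
  p_unif <- runif(10000)
  q <- fdr_qvalues(p_unif, "storey")
  expect_true(all(q >= 0 & q <= 1))
  expect_lt(mean(p_unif > 0.5) / 0.5 - 1, 0.05)  # sanity on the null
  # pi0 estimate near 1 on uniform p
  expect_equal(rmdskit:::.estimate_pi0(p_unif), 1, tolerance = 0.05)
  # Storey q <= BH q (pi0 <= 1) and monotone
  mix <- c(runif(900), rbeta(100, 0.2, 5))
  qs <- fdr_qvalues(mix, "storey"); qb <- fdr_qvalues(mix, "bh")
  expect_true(all(qs <= qb + 1e-12))
  ord <- order(mix)
  expect_true(!is.unsorted(qs[ord]))
  expect_error(fdr_qvalues(numeric(0)), "empty")
})
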