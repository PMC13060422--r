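# Design matrix for differential testing: intercept + response indicator
# (Responder = 1, so the effect is responder minus non-responder) + clinical
# covariates. Numeric covariates enter as-is; categorical covariates are
# one-hot encoded against their first level, after collapsing levels with
# < 2 samples into "other".
.differential_design <- function(metadata, covariates) {
  md <- data.table::as.data.table(metadata)
  resp <- as.character(md$response)
  lv <- sort(unique(resp))
  if (length(lv) != 2L) stop("response must have exactly 2 levels")
  pos <- if ("Responder" %in% lv) "Responder" else lv[2L]
  X <- cbind(`(Intercept)` = rep(1, nrow(md)),
             response = as.numeric(resp == pos))
  for (cv in covariates) {
    x <- md[[cv]]
    if (is.null(x)) stop("covariate '", cv, "' missing from metadata")
    if (is.numeric(x)) {
      X <- cbind(X, stats::setNames(data.frame(x), cv))
      colnames(X)[ncol(X)] <- cv
    } else {
      x <- as.character(x)
      tab <- table(x)
      rare <- names(tab)[tab < 2L]
      if (length(rare)) {
        warning("covariate '", cv, "': level(s) ",
                paste(rare, collapse = ", "), " collapsed to 'other'")
        x[x %in% rare] <- "other"
      }
      lvs <- sort(unique(x))
      for (l in lvs[-1L]) {
        X <- cbind(X, as.numeric(x == l))
        colnames(X)[ncol(X)] <- paste(cv, l, sep = ".")
      }
    }
  }
  as.matrix(X)
}

#' Consensus intra-patient correlation of repeated rMDS measurements
#'
#' Estimates, per bin, the intra-block (patient) correlation of the OLS
#' residuals of value ~ response + covariates via the one-way
#' random-intercept ANOVA decomposition, then pools bins on the Fisher-z
#' scale: `rho = tanh(mean(atanh(rho_bin)))` with per-bin values clipped to
#' (-0.99, 0.99). Used as the blocking correlation of the GLS fit in
#' [fit_differential()].
#'
#' @param values Samples x bins matrix.
#' @param metadata Sample metadata (needs sample_id, patient_id, response).
#' @param covariates Clinical covariate columns for the residualizing design.
#' @return Consensus rho (scalar), with per-bin values in
#'   `attr(, "per_bin")`.
#' @export
estimate_block_correlation <- function(values, metadata,
                                       covariates = character(0L)) {
  md <- .align_metadata(values, metadata)
  block <- as.character(md$patient_id)
  tab <- table(block)
  if (max(tab) < 2L) {
    warning("no repeated measures per patient: rho set to 0")
    return(structure(0, per_bin = rep(0, ncol(values))))
  }
  X <- .differential_design(md, covariates)
  R <- qr.resid(qr(X), values)
  N <- nrow(R)
  groups <- factor(block)
  kg <- nlevels(groups)
  G <- rowsum(R, groups)                       # patient sums, k x bins
  n_i <- as.numeric(table(groups))
  m_i <- G / n_i
  mbar <- colMeans(R)
  ssb <- colSums(n_i * sweep(m_i, 2L, mbar)^2)
  sst <- colSums(sweep(R, 2L, mbar)^2)
  ssw <- sst - ssb
  msb <- ssb / (kg - 1L)
  msw <- ssw / (N - kg)
  n0 <- (N - sum(n_i^2) / N) / (kg - 1L)
  rho <- (msb - msw) / (msb + (n0 - 1) * msw)
  rho <- pmin(pmax(rho, -0.99), 0.99)
  structure(tanh(mean(atanh(rho), na.rm = TRUE)), per_bin = rho)
}

# whitening transform for block-equicorrelated errors: within each patient
# block of size m, Sigma = (1-rho) I + rho J; Sigma^{-1/2} =
# (I - J/m)/sqrt(1-rho) + (J/m)/sqrt(1-rho+m*rho)
.block_whiten <- function(M, block, rho) {
  if (rho == 0) return(M)
  out <- M
  for (b in unique(block)) {
    idx <- which(block == b)
    m <- length(idx)
    if (m == 1L) { out[idx, ] <- M[idx, , drop = FALSE] / sqrt(1 - rho + rho); next }
    sub <- M[idx, , drop = FALSE]
    mu <- colMeans(sub)
    ctr <- sweep(sub, 2L, mu)
    out[idx, ] <- ctr / sqrt(1 - rho) +
      matrix(mu, nrow = m, ncol = ncol(M), byrow = TRUE) /
        sqrt(1 - rho + m * rho)
  }
  out
}

# Smyth-style moment estimation of the scaled inverse-chi^2 variance prior
# (d0, s0^2) from log s^2, and the posterior (squeezed) variances
.squeeze_var <- function(s2, df, prior_df = NULL) {
  ok <- is.finite(s2) & s2 > 0
  e <- log(s2[ok])
  z <- e - digamma(df / 2) + log(df / 2)
  emean <- mean(z)
  evar <- stats::var(z) - trigamma(df / 2)
  if (!is.null(prior_df)) {
    d0 <- prior_df
    s02 <- if (is.infinite(d0)) exp(emean) else
      exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(emean)
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  post <- s2
  if (is.infinite(d0)) {
    post[ok] <- s02
  } else {
    post[ok] <- (d0 * s02 + df * s2[ok]) / (d0 + df)
  }
  list(df_prior = d0, var_prior = s02, var_post = post)
}

.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Moderated differential testing of rMDS between response groups
#'
#' Per bin, fits a generalized least squares model of the (corrected,
#' standardized) value on response plus clinical covariates, with
#' block-equicorrelated errors within patient at correlation `rho` (from
#' [estimate_block_correlation()]). Residual variances are squeezed toward a
#' scaled inverse-chi-squared prior fitted by moment matching on log s^2
#' (empirical Bayes), and the response effect is tested with a moderated
#' t-statistic on `d0 + d` degrees of freedom. P-values are two-sided and
#' corrected by [fdr_qvalues()].
#'
#' @param values Samples x bins matrix.
#' @param metadata Sample metadata.
#' @param covariates Clinical covariate columns (e.g. age, gender, smoking,
#'   alcohol).
#' @param rho Intra-patient correlation (default: estimated internally).
#' @param weights Optional per-sample weights (default 1).
#' @param prior_df Optional forced prior degrees of freedom d0 (`Inf` gives
#'   the fully pooled-variance limit); default: estimated by moment
#'   matching.
#' @param q_method `"storey"` (default) or `"bh"`.
#' @return A `differential_table` data.table (bin, effect, se, t, p, q)
#'   sorted by q, with model metadata in attributes (`rho`, `df_prior`,
#'   `var_prior`, `n_tested`, `n_flagged`).
#' @export
fit_differential <- function(values, metadata, covariates = character(0L),
                             rho = NULL, weights = NULL, prior_df = NULL,
                             q_method = c("storey", "bh")) {
  q_method <- match.arg(q_method)
  md <- .align_metadata(values, metadata)
  if (is.null(rho)) {
    rho <- as.numeric(estimate_block_correlation(values, md, covariates))
  }
  X <- .differential_design(md, covariates)
  Y <- values
  if (!is.null(weights)) {
    sw <- sqrt(weights)
    X <- X * sw
    Y <- Y * sw
  }
  block <- as.character(md$patient_id)
  Xw <- .block_whiten(X, block, rho)
  Yw <- .block_whiten(Y, block, rho)
  qx <- qr(Xw)
  if (qx$rank < ncol(Xw)) stop("differential design is rank deficient")
  beta <- qr.coef(qx, Yw)
  res <- qr.resid(qx, Yw)
  df <- nrow(Xw) - ncol(Xw)
  s2 <- colSums(res^2) / df
  xtxi <- chol2inv(qr.R(qx))
  j <- match("response", colnames(X))
  unit_var <- xtxi[j, j]

  sq <- .squeeze_var(s2, df, prior_df = prior_df)
  se <- sqrt(unit_var * sq$var_post)
  eff <- beta[j, ]
  tstat <- eff / se
  df_total <- sq$df_prior + df
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  flagged <- !is.finite(p)
  q <- rep(NA_real_, length(p))
  q[!flagged] <- fdr_qvalues(p[!flagged], method = q_method)

  out <- data.table::data.table(bin = colnames(values), effect = eff,
                                se = se, t = tstat, p = p, q = q)
  data.table::setorder(out, q, p, na.last = TRUE)
  data.table::setattr(out, "rho", rho)
  data.table::setattr(out, "df_prior", sq$df_prior)
  data.table::setattr(out, "var_prior", sq$var_prior)
  data.table::setattr(out, "df_residual", df)
  data.table::setattr(out, "n_tested", sum(!flagged))
  data.table::setattr(out, "n_flagged", sum(flagged))
  data.table::setattr(out, "class",
                      c("differential_table", class(out)))
  out
}

#' FDR q-values
#'
#' Default is the Storey procedure: the null proportion `pi0` is estimated
#' on a lambda grid (0.05--0.95) with cubic-spline smoothing, and q-values
#' are `pi0`-scaled step-up FDR estimates, monotone in p. Method `"bh"`
#' gives Benjamini-Hochberg (equivalent to `pi0 = 1`).
#'
#' @param p P-values in [0, 1].
#' @param method `"storey"` or `"bh"`.
#' @return Q-values, same order as `p`.
#' @export
fdr_qvalues <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  if (!length(p)) stop("empty p-value vector")
  stopifnot(all(p >= 0 & p <= 1))
  if (method == "bh") return(stats::p.adjust(p, "BH"))
  pi0 <- .estimate_pi0(p)
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * n * p[o] / rank(p, ties.method = "max")[o]))[ro]
  q
}

.estimate_pi0 <- function(p) {
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1L))
  if (length(p) < 100L || all(pi0_l == 0)) {
    return(min(1, max(pi0_l[length(pi0_l)], 0), 1))
  }
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1 / length(p)), 1)
}
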