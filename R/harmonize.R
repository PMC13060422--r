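# sum-to-zero contrast encoding with stored level order; rows for levels not
# in `levels` encode to zero (grand-mean correction only)
.sum_encode <- function(x, levels) {
  x <- as.character(x)
  L <- length(levels)
  if (L < 2L) stop("factor needs >= 2 levels, got: ",
                   paste(levels, collapse = ", "))
  m <- matrix(0, nrow = length(x), ncol = L - 1L,
              dimnames = list(NULL, paste0("c", seq_len(L - 1L))))
  for (j in seq_len(L - 1L)) m[x == levels[j], j] <- 1
  m[x == levels[L], ] <- -1
  m
}

.batch_design <- function(metadata, batch_factors, levels_list) {
  cols <- lapply(batch_factors, function(f) {
    enc <- .sum_encode(metadata[[f]], levels_list[[f]])
    colnames(enc) <- paste(f, levels_list[[f]][-length(levels_list[[f]])],
                           sep = ".")
    enc
  })
  do.call(cbind, cols)
}

#' Fit a response-preserving batch-correction model
#'
#' Per bin, fits value ~ batch factors + preserved covariate by ordinary
#' least squares with sum-to-zero contrasts on every factor, and stores the
#' batch coefficients so they can later be subtracted from the fit set or
#' applied frozen to held-out samples (see [apply_correction()]). The
#' preserved covariate (treatment response by default) is part of the design
#' so its signal is never absorbed by the batch terms, and its coefficients
#' are never subtracted.
#'
#' @param values Samples x bins numeric matrix (rownames = sample ids).
#' @param metadata data.frame with one row per sample, aligned to `values`
#'   by the `sample_id` column.
#' @param batch_factors Metadata columns to remove (default institute,
#'   isolation date, library date).
#' @param preserve Metadata column carrying the biological signal to keep.
#' @return A `correction_model`: levels per factor, batch coefficient matrix
#'   (batch columns x bins), fit sample ids.
#' @export
fit_correction <- function(values, metadata,
                           batch_factors = c("institute", "isolation_date",
                                             "library_date"),
                           preserve = "response") {
  md <- .align_metadata(values, metadata)
  levels_list <- lapply(batch_factors, function(f) {
    lv <- unique(as.character(md[[f]]))
    if (length(lv) < 2L) stop("batch factor '", f,
                              "' has fewer than 2 levels in the fit set")
    sort(lv)
  })
  names(levels_list) <- batch_factors
  pres_levels <- sort(unique(as.character(md[[preserve]])))
  Xb <- .batch_design(md, batch_factors, levels_list)
  Xp <- .sum_encode(md[[preserve]], pres_levels)
  colnames(Xp) <- paste(preserve, pres_levels[-length(pres_levels)], sep = ".")
  X <- cbind(`(Intercept)` = 1, Xb, Xp)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design is rank deficient; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qx, values)
  bcols <- colnames(Xb)
  structure(list(batch_factors = batch_factors, preserve = preserve,
                 levels = levels_list, preserve_levels = pres_levels,
                 beta_batch = beta[bcols, , drop = FALSE],
                 fit_samples = md$sample_id,
                 bins = colnames(values)),
            class = "correction_model")
}

#' Apply a fitted batch correction to a matrix
#'
#' Subtracts the batch design times the frozen batch coefficients:
#' `corrected = values - X_batch %*% beta_batch`. The preserved covariate's
#' term is untouched, and factor levels unseen at fit time encode to the
#' zero vector under sum contrasts (grand-mean correction only, with a
#' warning) — no parameter is ever re-estimated from the new samples.
#'
#' @param values Samples x bins matrix with the model's bin set.
#' @param metadata Metadata rows for those samples.
#' @param model A `correction_model` from [fit_correction()].
#' @return Corrected matrix of the same shape.
#' @export
apply_correction <- function(values, metadata, model) {
  stopifnot(inherits(model, "correction_model"))
  if (!identical(colnames(values), model$bins)) {
    stop("bin set mismatch between matrix and correction model")
  }
  md <- .align_metadata(values, metadata)
  for (f in model$batch_factors) {
    unseen <- setdiff(unique(as.character(md[[f]])), model$levels[[f]])
    if (length(unseen)) {
      warning("unseen ", f, " level(s) ", paste(unseen, collapse = ", "),
              ": grand-mean correction only")
    }
  }
  Xb <- .batch_design(md, model$batch_factors, model$levels)
  values - Xb %*% model$beta_batch
}

.align_metadata <- function(values, metadata) {
  md <- data.table::as.data.table(metadata)
  stopifnot("sample_id" %in% names(md))
  idx <- match(rownames(values), md$sample_id)
  if (anyNA(idx)) stop("samples missing from metadata: ",
                       paste(rownames(values)[is.na(idx)], collapse = ", "))
  md[idx]
}

#' Standardize a matrix per bin across samples
#'
#' Centers and scales each bin (column) to mean 0, SD 1 (population SD);
#' zero-variance bins are dropped with a message. `scaler`, when given,
#' reuses a previously fitted center/scale (frozen standardization for
#' held-out data).
#'
#' @param values Samples x bins matrix.
#' @param scaler Optional result of a previous call (its `center`, `scale`,
#'   `keep` are reused).
#' @return The standardized matrix, with the fitted scaler in
#'   `attr(, "scaler")`.
#' @export
standardize_bins <- function(values, scaler = NULL) {
  if (is.null(scaler)) {
    ctr <- colMeans(values)
    sc <- sqrt(colMeans(sweep(values, 2L, ctr)^2))
    keep <- sc > 0
    if (!all(keep)) message(sum(!keep), " zero-variance bin(s) dropped")
    scaler <- list(center = ctr[keep], scale = sc[keep],
                   keep = colnames(values)[keep])
  }
  v <- values[, scaler$keep, drop = FALSE]
  out <- sweep(sweep(v, 2L, scaler$center), 2L, scaler$scale, "/")
  attr(out, "scaler") <- scaler
  out
}

#' Truncated singular value decomposition of a feature matrix
#'
#' Decomposes `values = U D V'` and keeps the first `n_components` score
#' columns `U D` (no centering, matching the truncated-SVD convention on an
#' already standardized matrix). Component signs are canonicalized so the
#' largest-magnitude loading of each component is positive, making the
#' embedding reproducible across runs and platforms.
#'
#' @param values Samples x bins matrix.
#' @param n_components Number of components (default 6).
#' @return An `svd_embedding`: `scores` (samples x n_components), `d`
#'   (all singular values), `v` (loadings for the kept components),
#'   `explained_variance` (fractions, all components).
#' @export
svd_reduce <- function(values, n_components = 6L) {
  n_components <- as.integer(n_components)
  if (n_components > min(dim(values))) {
    stop("n_components exceeds min(samples, bins)")
  }
  s <- svd(values)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- s$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1L))
  flip[flip == 0] <- 1
  v <- sweep(s$v[, seq_len(n_components), drop = FALSE], 2L, flip, "*")
  scores <- sweep(s$u[, seq_len(n_components), drop = FALSE], 2L,
                  flip * s$d[seq_len(n_components)], "*")
  rownames(scores) <- rownames(values)
  structure(list(scores = scores, d = s$d, v = v,
                 n_components = n_components,
                 explained_variance = s$d^2 / sum(s$d^2)),
            class = "svd_embedding")
}

#' Project new samples onto a fitted SVD basis
#'
#' @param embedding An `svd_embedding` from [svd_reduce()].
#' @param values New samples x bins matrix over the same bins.
#' @return Scores matrix (samples x n_components).
#' @export
project_svd <- function(embedding, values) {
  stopifnot(inherits(embedding, "svd_embedding"))
  values %*% embedding$v
}

#' Silhouette score of a labeled feature space
#'
#' Per sample i with mean intra-label distance a(i) and mean distance b(i)
#' to the nearest other label, the score is (b - a) / max(a, b); samples in
#' a singleton label, or with a = b = 0 (identical points), score 0.
#' Euclidean distances. Used to quantify responder/non-responder separation
#' before and after batch correction.
#'
#' @param features Samples x features matrix.
#' @param labels Vector of group labels (>= 2 groups).
#' @return List with `scores` (per sample) and `mean`.
#' @export
silhouette_separation <- function(features, labels) {
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2L) stop("need >= 2 labels")
  d <- as.matrix(stats::dist(features))
  n <- length(labels)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    if (length(same) < 2L) {
      warning("singleton cluster '", labels[i], "': score set to 0")
      scores[i] <- 0
      next
    }
    a <- mean(d[i, setdiff(same, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(d[i, labels == l])
    }, numeric(1L)))
    m <- max(a, b)
    scores[i] <- if (m == 0) 0 else (b - a) / m
  }
  list(scores = scores, mean = mean(scores))
}
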