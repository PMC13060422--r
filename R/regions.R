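#' Cluster differential bins by their longitudinal pattern
#'
#' Each significant bin becomes a feature vector of its values across all
#' samples, ordered by (response group, patient, timepoint) so that bins
#' with the same response-by-timepoint dynamics are close in Euclidean
#' distance. Bins are hierarchically clustered with Ward's method and the
#' tree cut to exactly `n_clusters`; labels are renumbered by descending
#' cluster size for reproducibility (dendrogram order is not portable).
#'
#' @param values Samples x bins matrix.
#' @param metadata Sample metadata (response, patient_id, timepoint).
#' @param bins Character vector of significant bin names (columns of
#'   `values`).
#' @param n_clusters Number of clusters (default 3).
#' @param timepoint_order Ordering of timepoints for the feature layout.
#' @return A `cluster_assignment` data.table (bin, cluster) with the hclust
#'   object in `attr(, "hclust")`.
#' @export
cluster_bins <- function(values, metadata, bins, n_clusters = 3L,
                         timepoint_order = c("Screen", "Day0", "AdjWk1")) {
  if (length(bins) < n_clusters) stop("fewer bins than clusters")
  stopifnot(all(bins %in% colnames(values)))
  md <- .align_metadata(values, metadata)
  ti <- match(md$timepoint, timepoint_order)
  ord <- order(md$response, md$patient_id, ti)
  feat <- t(values[ord, bins, drop = FALSE])
  hc <- stats::hclust(stats::dist(feat), method = "ward.D2")
  raw <- stats::cutree(hc, k = n_clusters)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  out <- data.table::data.table(bin = bins,
                                cluster = unname(relabel[as.character(raw)]))
  data.table::setattr(out, "hclust", hc)
  data.table::setattr(out, "class", c("cluster_assignment", class(out)))
  out
}

#' Average rMDS trajectories per cluster and response group
#'
#' For each cluster, collapses each sample to its mean value over the
#' cluster's bins, averages within patient per timepoint, and summarizes per
#' (cluster, response, timepoint) stratum as the across-patient mean with a
#' 95% t-interval. Strata with one patient get a degenerate interval.
#'
#' @param values Samples x bins matrix.
#' @param assignment A `cluster_assignment`.
#' @param metadata Sample metadata.
#' @return data.table (cluster, response, timepoint, n_patients, mean, lo,
#'   hi).
#' @export
trajectory_summary <- function(values, assignment, metadata) {
  md <- .align_metadata(values, metadata)
  out <- list()
  for (cl in sort(unique(assignment$cluster))) {
    bins <- assignment$bin[assignment$cluster == cl]
    sv <- rowMeans(values[, bins, drop = FALSE])
    dt <- data.table::data.table(
      value = sv, response = md$response,
      patient_id = md$patient_id, timepoint = md$timepoint)
    pat <- dt[, .(value = mean(value)),
              by = .(response, patient_id, timepoint)]
    sm <- pat[, {
      m <- mean(value); s <- stats::sd(value); n <- .N
      half <- if (n > 1L && is.finite(s)) stats::qt(0.975, n - 1L) * s / sqrt(n) else 0
      .(n_patients = n, mean = m, lo = m - half, hi = m + half)
    }, by = .(response, timepoint)]
    sm[, cluster := cl]
    out[[length(out) + 1L]] <- sm
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("cluster", "response", "timepoint",
                                 "n_patients", "mean", "lo", "hi"))
  res[]
}

# telomere distances of n random bins of the layout's bin width placed
# uniformly on the layout's chromosomes with probability proportional to
# chromosome length
.random_bin_distances <- function(layout, n) {
  L <- layout$chroms
  w <- layout$bin_size
  ci <- sample.int(length(L), n, replace = TRUE, prob = L)
  maxs <- pmax(L[ci] - w, 0L)
  starts <- floor(stats::runif(n) * (maxs + 1L))
  mid <- floor((starts + pmin(starts + w, L[ci])) / 2)
  pmin(mid, L[ci] - mid)
}

#' Telomere-proximity enrichment of a bin cluster
#'
#' Tests whether a cluster of bins lies closer to chromosome ends than
#' random bins. The null is `n_null` bins of the layout's bin width placed
#' uniformly at random (chromosome drawn proportional to its length; null
#' bins may overlap anything). Two tests are reported: a one-sided
#' Mann-Whitney U of observed vs null distances (alternative: observed
#' stochastically smaller), and a permutation test on the mean distance,
#' `p = (1 + #\{perm mean <= observed mean\}) / (n_perm + 1)` where each
#' permutation resamples `|cluster|` distances from the null pool.
#'
#' @param bin_ids Integer bin ids of the cluster (>= 2).
#' @param layout A `genome_layout`.
#' @param n_null Null pool size (default 100000).
#' @param n_perm Number of permutations (default 100000).
#' @param seed Integer seed.
#' @param statistic `"mean"` (default) or `"median"` permutation statistic.
#' @return An `enrichment_result` list: observed distances and mean, null
#'   mean, `mw_p`, `perm_p`, `n_perm`, direction.
#' @export
telomere_enrichment <- function(bin_ids, layout, n_null = 100000L,
                                n_perm = 100000L, seed = 1L,
                                statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (length(bin_ids) < 2L) stop("need >= 2 cluster bins")
  if (any(table(layout$bins$chrom) < 2L)) {
    warning("a chromosome has a single bin; test still runs")
  }
  obs <- telomere_distance(bin_ids, layout)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- .random_bin_distances(layout, n_null)
  mw <- stats::wilcox.test(obs, null, alternative = "less", exact = FALSE)
  stat_fun <- if (statistic == "mean") mean else stats::median
  obs_stat <- stat_fun(obs)
  m <- length(obs)
  perm <- matrix(sample(null, n_perm * m, replace = TRUE), nrow = m)
  perm_stat <- if (statistic == "mean") colMeans(perm)
               else apply(perm, 2L, stats::median)
  perm_p <- (1 + sum(perm_stat <= obs_stat)) / (n_perm + 1)
  structure(list(bin_ids = bin_ids, observed = obs,
                 observed_stat = obs_stat, null_stat = stat_fun(null),
                 statistic = statistic,
                 mw_p = mw$p.value, perm_p = perm_p, n_perm = n_perm,
                 n_null = n_null,
                 direction = if (obs_stat < stat_fun(null)) "telomere-proximal"
                             else "interior"),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "telomere enrichment: %d bins, %s distance %.0f vs null %.0f (%s)\n",
    length(x$bin_ids), x$statistic, x$observed_stat, x$null_stat,
    x$direction))
  cat(sprintf("  Mann-Whitney p = %.3g, permutation p = %.3g (n_perm = %d)\n",
              x$mw_p, x$perm_p, x$n_perm))
  invisible(x)
}
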