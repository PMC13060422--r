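#' Regional motif diversity score from end-motif counts
#'
#' For each genomic bin j with motif relative frequencies
#' \eqn{P_{i,j} = c_{i,j} / \sum_i c_{i,j}}, the rMDS is the normalized
#' Shannon entropy
#' \deqn{rMDS_j = \sum_i -P_{i,j} \log P_{i,j} / \log(4^k)}
#' with \eqn{0 \log 0 := 0} and no pseudocounts, so the score is 1 for
#' uniform motif usage over all \eqn{4^k} motifs and 0 when a single motif
#' carries every end. The value is invariant to the logarithm base. Bins with
#' fewer than `min_ends` ends are reported as missing.
#'
#' @param counts A `motif_counts` object, or a bins x motifs count matrix.
#' @param min_ends Minimum ends per bin for a defined score (default 100).
#' @param layout Optional `genome_layout` carried into the profile.
#' @return An `rmds_profile`: data.table (bin_id, n_ends, rmds, z_rmds = NA
#'   until [zscore_transform()]) plus metadata attributes.
#' @export
rmds_from_counts <- function(counts, min_ends = 100L, layout = NULL) {
  if (inherits(counts, "motif_counts")) {
    mat <- counts$counts
    k <- counts$k; end_side <- counts$end_side; sid <- counts$sample_id
  } else {
    mat <- as.matrix(counts)
    k <- as.integer(round(log(ncol(mat), 4)))
    if (4L^k != ncol(mat)) stop("column count is not a power of 4")
    end_side <- NA_character_; sid <- NA_character_
  }
  stopifnot(min_ends >= 1)
  tot <- rowSums(mat)
  rmds <- rep(NA_real_, nrow(mat))
  ok <- tot >= min_ends
  if (!any(ok)) stop("no usable bins: all bins below min_ends")
  p <- mat[ok, , drop = FALSE] / tot[ok]
  h <- -rowSums(ifelse(p > 0, p * log(p), 0)) + 0  # + 0 clears IEEE -0
  rmds[ok] <- h / log(ncol(mat))

  prof <- data.table::data.table(
    bin_id = if (!is.null(rownames(mat))) as.integer(rownames(mat))
             else seq_len(nrow(mat)),
    n_ends = as.numeric(tot), rmds = rmds, z_rmds = NA_real_)
  structure(list(profile = prof, k = k, end_side = end_side,
                 sample_id = sid, min_ends = as.integer(min_ends),
                 layout = layout),
            class = "rmds_profile")
}

#' @export
print.rmds_profile <- function(x, ...) {
  p <- x$profile
  cat("rmds_profile:", nrow(p), "bins,", sum(!is.na(p$rmds)), "defined;",
      "mean rMDS", round(mean(p$rmds, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' Z-score transform an rMDS profile across bins
#'
#' Standardizes the defined rMDS values of one sample across its genome:
#' \eqn{Z_j = (rMDS_j - \mu) / \sigma} with the population standard
#' deviation over defined bins. Missing bins stay missing.
#'
#' @param profile An `rmds_profile` from [rmds_from_counts()].
#' @return The profile with `z_rmds` filled in.
#' @export
zscore_transform <- function(profile) {
  stopifnot(inherits(profile, "rmds_profile"))
  x <- profile$profile$rmds
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("degenerate profile: fewer than 2 defined bins")
  mu <- mean(x[ok])
  sigma <- sqrt(mean((x[ok] - mu)^2))
  if (sigma == 0) stop("degenerate profile: zero variance across bins")
  profile$profile[, z_rmds := (rmds - mu) / sigma]
  profile
}

#' Sliding-window rMDS track
#'
#' Computes a locus-resolution rMDS track: windows are placed every `step`
#' bp along each chromosome and each window's value is the (raw, not
#' z-scored) rMDS of all fragment ends within `flank` bp of the window
#' center, i.e. an effective window of `2 * flank` bp (defaults 10 kb step,
#' 250 kb flank = 500 kb windows). Windows with fewer than `min_ends` ends
#' are omitted.
#'
#' @param fragments A `fragment_set` or fragment table.
#' @param reference FASTA path or named sequences.
#' @param layout A `genome_layout` (chromosome extents).
#' @param step Window spacing in bp.
#' @param flank Half-width of the window in bp; `flank >= step` required.
#' @param k Motif length.
#' @param min_ends Minimum ends per window.
#' @param end_side Which end to profile.
#' @return data.table (chrom, start, end, n_ends, rmds) in bedGraph order;
#'   use [write_bedgraph()] to export.
#' @export
sliding_rmds <- function(fragments, reference, layout, step = 10000L,
                         flank = 250000L, k = 4L, min_ends = 100L,
                         end_side = "five_prime") {
  stopifnot(flank >= step)
  recs <- .end_motif_records(fragments, reference, k, end_side)
  n_motifs <- 4L^k
  out <- vector("list", length(layout$chroms))
  for (i in seq_along(layout$chroms)) {
    ch <- names(layout$chroms)[i]
    L <- layout$chroms[[i]]
    if (step > L) {
      warning("step exceeds length of ", ch, "; empty track")
      next
    }
    centers <- seq.int(from = step %/% 2L, to = L - 1L, by = step)
    sub <- recs[chrom == ch][order(pos)]
    if (!nrow(sub)) next
    lo <- findInterval(centers - flank - 1L, sub$pos) + 1L
    hi <- findInterval(centers + flank, sub$pos)
    vals <- rep(NA_real_, length(centers))
    nend <- hi - lo + 1L
    for (w in seq_along(centers)) {
      if (nend[w] < min_ends) next
      cnt <- tabulate(sub$motif[lo[w]:hi[w]] + 1L, nbins = n_motifs)
      p <- cnt[cnt > 0] / nend[w]
      vals[w] <- -sum(p * log(p)) / log(n_motifs)
    }
    keep <- !is.na(vals)
    if (!any(keep)) next
    out[[i]] <- data.table::data.table(
      chrom = ch,
      start = pmax(centers[keep] - step %/% 2L, 0L),
      end = pmin(centers[keep] + (step - step %/% 2L), L),
      n_ends = nend[keep], rmds = vals[keep])
  }
  data.table::rbindlist(out)
}

#' Write a track as bedGraph
#'
#' @param track data.table with chrom, start, end and a value column.
#' @param path Output path.
#' @param value Name of the value column (default `"rmds"`).
#' @export
write_bedgraph <- function(track, path, value = "rmds") {
  data.table::fwrite(track[, c("chrom", "start", "end", value), with = FALSE],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Depth-stability analysis of the rMDS profile
#'
#' Downsamples a fragment set to a series of relative depths, recomputes the
#' rMDS profile at each level, and reports the Pearson correlation with the
#' full-depth profile over bins defined at both depths — the signal-recovery
#' curve used to judge how much sequencing a stable profile needs. When
#' group labels are supplied a silhouette score of the label separation at
#' each level is added.
#'
#' @param fragments A `fragment_set` or fragment table (full depth).
#' @param reference,layout,k,min_ends As in [extract_end_motifs()] /
#'   [rmds_from_counts()].
#' @param levels Strictly decreasing depth fractions in (0, 1].
#' @param seed Integer seed for the downsampling.
#' @return A `stability_report` data.table (level, n_bins, pearson_r).
#' @export
stability_analysis <- function(fragments, reference, layout,
                               levels = c(0.5, 0.25, 0.1, 0.05),
                               k = 4L, min_ends = 100L, seed = 1L) {
  stopifnot(all(levels > 0))
  if (any(levels > 1)) stop("level deeper than the input (fraction > 1)")
  if (is.unsorted(rev(levels), strictly = TRUE)) {
    stop("levels must be strictly decreasing")
  }
  full <- rmds_from_counts(
    extract_end_motifs(fragments, reference, layout, k = k),
    min_ends = min_ends)$profile$rmds
  res <- data.table::data.table(level = levels, n_bins = NA_integer_,
                                pearson_r = NA_real_)
  for (i in seq_along(levels)) {
    ds <- downsample_fragments(fragments, levels[i], seed = seed + i)
    prof <- rmds_from_counts(
      extract_end_motifs(ds, reference, layout, k = k),
      min_ends = min_ends)$profile$rmds
    ok <- !is.na(full) & !is.na(prof)
    res[i, n_bins := sum(ok)]
    if (sum(ok) >= 3L) res[i, pearson_r := stats::cor(full[ok], prof[ok])]
  }
  res[]
}
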