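#' Build a binned genome layout
#'
#' Tiles each chromosome with fixed-width, non-overlapping, 0-based half-open
#' bins (the terminal bin of a chromosome may be shorter), and marks bins as
#' unusable when they overlap a blacklist or fall below a mappability floor.
#' The layout is the coordinate authority for every downstream stage: bins are
#' identified by their index in the layout table.
#'
#' @param chrom_sizes Path to a two-column chromosome-sizes TSV
#'   (name, length), or a data.frame with columns `chrom` and `length`.
#' @param bin_size Bin width in bp (default 500000, the genome-wide analysis
#'   resolution; tests use smaller bins).
#' @param blacklist Optional BED file (or data.frame chrom/start/end) of
#'   excluded regions. A bin is masked when more than `blacklist_max_overlap`
#'   of its width is blacklisted; fragments overlapping any blacklist interval
#'   are additionally removed record-wise by [filter_fragments()].
#' @param mappability Optional BED/bedGraph (chrom, start, end, score) of
#'   mappability; a bin is masked when its mean mappability (unreported bases
#'   count as 0) is below `mappability_min`.
#' @param mappability_min Mappability floor (default 0.9).
#' @param blacklist_max_overlap Masking threshold on the blacklisted fraction
#'   of a bin (default 0.5).
#' @return A `genome_layout` object: list with `chroms` (named lengths),
#'   `bin_size`, and `bins` (data.table: bin_id, chrom, start, end, usable).
#' @export
load_layout <- function(chrom_sizes, bin_size = 500000L,
                        blacklist = NULL, mappability = NULL,
                        mappability_min = 0.9,
                        blacklist_max_overlap = 0.5) {
  stopifnot(bin_size > 0)
  sizes <- .read_chrom_sizes(chrom_sizes)
  if (anyDuplicated(sizes$chrom)) {
    stop("duplicate chromosome names in sizes table: ",
         paste(unique(sizes$chrom[duplicated(sizes$chrom)]), collapse = ", "))
  }
  if (any(sizes$length <= 0)) stop("non-positive chromosome length")

  bins <- data.table::rbindlist(lapply(seq_len(nrow(sizes)), function(i) {
    L <- sizes$length[i]
    starts <- seq.int(0L, L - 1L, by = bin_size)
    data.table::data.table(chrom = sizes$chrom[i], start = starts,
                           end = pmin(starts + bin_size, L))
  }))
  bins[, `:=`(bin_id = seq_len(.N), usable = TRUE)]
  data.table::setcolorder(bins, c("bin_id", "chrom", "start", "end", "usable"))

  bin_gr <- GenomicRanges::GRanges(
    bins$chrom, IRanges::IRanges(bins$start + 1L, bins$end))

  if (!is.null(blacklist)) {
    bl <- .read_bed3(blacklist)
    if (nrow(bl)) {
      bl_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        bl$chrom, IRanges::IRanges(bl$start + 1L, bl$end)))
      cov <- rep(0, nrow(bins))
      hits <- GenomicRanges::findOverlaps(bin_gr, bl_gr)
      if (length(hits)) {
        ov <- IRanges::width(IRanges::pintersect(
          bin_gr[S4Vectors::queryHits(hits)], bl_gr[S4Vectors::subjectHits(hits)]))
        agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
        cov[as.integer(names(agg))] <- agg
      }
      frac <- cov / (bins$end - bins$start)
      bins[frac > blacklist_max_overlap, usable := FALSE]
    }
  }

  if (!is.null(mappability)) {
    mp <- .read_bedgraph(mappability)
    mp_gr <- GenomicRanges::GRanges(
      mp$chrom, IRanges::IRanges(mp$start + 1L, mp$end), score = mp$score)
    tot <- rep(0, nrow(bins))
    hits <- GenomicRanges::findOverlaps(bin_gr, mp_gr)
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        bin_gr[S4Vectors::queryHits(hits)], mp_gr[S4Vectors::subjectHits(hits)]))
      wsum <- tapply(ov * mp$score[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits), sum)
      tot[as.integer(names(wsum))] <- wsum
    }
    mean_map <- tot / (bins$end - bins$start)
    bins[mean_map < mappability_min, usable := FALSE]
  }

  structure(list(chroms = stats::setNames(sizes$length, sizes$chrom),
                 bin_size = as.integer(bin_size),
                 bins = bins),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chroms), "chromosomes,",
      nrow(x$bins), "bins of", x$bin_size, "bp (",
      sum(x$bins$usable), "usable )\n")
  invisible(x)
}

#' Distance from a bin midpoint to the nearest chromosome end
#'
#' The telomere-proximity statistic: `min(mid, L - mid)` for bin midpoint
#' `mid = floor((start + end) / 2)` on a chromosome of length `L`.
#'
#' @param bin_ids Integer bin ids (see [load_layout()]).
#' @param layout A `genome_layout`.
#' @return Numeric vector of distances in bp.
#' @export
telomere_distance <- function(bin_ids, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  b <- layout$bins[match(bin_ids, layout$bins$bin_id)]
  if (anyNA(b$chrom)) stop("bin id not in layout")
  mid <- floor((b$start + b$end) / 2)
  L <- unname(layout$chroms[b$chrom])
  pmin(mid, L - mid)
}

# global bin index (row in layout$bins) for 0-based positions; NA if off-layout
.pos_to_bin <- function(chrom, pos, layout) {
  off <- c(0L, cumsum(ceiling(layout$chroms / layout$bin_size)))
  ci <- match(chrom, names(layout$chroms))
  within <- pos %/% layout$bin_size
  bad <- is.na(ci) | pos < 0 | pos >= layout$chroms[ci]
  out <- off[ci] + within + 1L
  out[bad] <- NA_integer_
  out
}

.read_chrom_sizes <- function(x) {
  if (is.data.frame(x)) {
    dt <- data.table::as.data.table(x)
    data.table::setnames(dt, 1:2, c("chrom", "length"))
  } else {
    dt <- data.table::fread(x, header = FALSE, select = 1:2,
                            col.names = c("chrom", "length"))
  }
  dt[, chrom := as.character(chrom)]
  dt[, length := as.integer(length)]
  dt[]
}

.read_bed3 <- function(x) {
  if (is.data.frame(x)) {
    dt <- data.table::as.data.table(x)
    data.table::setnames(dt, 1:3, c("chrom", "start", "end"))
  } else {
    dt <- data.table::fread(x, header = FALSE, select = 1:3,
                            col.names = c("chrom", "start", "end"))
  }
  if (nrow(dt) && any(dt$start >= dt$end)) stop("malformed interval in BED")
  dt[]
}

.read_bedgraph <- function(x) {
  if (is.data.frame(x)) {
    dt <- data.table::as.data.table(x)
    data.table::setnames(dt, 1:4, c("chrom", "start", "end", "score"))
  } else {
    dt <- data.table::fread(x, header = FALSE, select = 1:4,
                            col.names = c("chrom", "start", "end", "score"))
  }
  dt[]
}
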