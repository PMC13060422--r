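#' Read fragment intervals from a BED-like file
#'
#' Accepts 3--6 column BED (chrom, start, end, name, mapq, strand), plain or
#' gzipped, 0-based half-open. No filtering is applied here; see
#' [filter_fragments()].
#'
#' @param path File path (optionally `.gz`).
#' @return A data.table with columns chrom, start, end and, when present,
#'   name, mapq, strand.
#' @export
read_fragments <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  nm <- c("chrom", "start", "end", "name", "mapq", "strand")[seq_len(ncol(dt))]
  data.table::setnames(dt, nm)
  dt[, chrom := as.character(chrom)]
  dt[]
}

#' Quality-filter fragment records
#'
#' Applies the fragment-level QC used throughout the pipeline: mapping
#' quality >= `min_mapq`, fragment length within `[min_len, max_len]`
#' (inclusive; 50--350 bp by default, the mono- to di-nucleosomal range),
#' chromosome present in the layout, and no overlap with blacklist intervals.
#' Records failing `start < end` are rejected, never silently dropped. Every
#' rejection is attributed to the first failing rule so the counts in the
#' filter log sum to the number of removed records.
#'
#' @param records data.table/data.frame of fragments (chrom, start, end,
#'   optional mapq). A missing mapq column passes the mapq rule (inputs are
#'   assumed pre-filtered) and is noted in the log.
#' @param layout A `genome_layout`.
#' @param blacklist Optional BED (path or data.frame) of excluded regions;
#'   any overlapping fragment is removed.
#' @param min_mapq,min_len,max_len QC thresholds.
#' @return A `fragment_set`: list with `fragments` (data.table) and `log`
#'   (named rejection counts plus `n_in`, `n_kept`).
#' @export
filter_fragments <- function(records, layout, blacklist = NULL,
                             min_mapq = 30L, min_len = 50L, max_len = 350L) {
  stopifnot(inherits(layout, "genome_layout"))
  dt <- data.table::as.data.table(records)
  stopifnot(all(c("chrom", "start", "end") %in% names(dt)))
  n_in <- nrow(dt)
  log <- c(malformed = 0L, chrom = 0L, mapq = 0L, length = 0L, blacklist = 0L)
  has_mapq <- "mapq" %in% names(dt)

  reason <- rep(NA_character_, n_in)
  bad <- dt$start >= dt$end
  reason[bad] <- "malformed"
  off <- is.na(reason) & !(dt$chrom %in% names(layout$chroms))
  reason[off] <- "chrom"
  if (has_mapq) {
    lowq <- is.na(reason) & (is.na(dt$mapq) | dt$mapq < min_mapq)
    reason[lowq] <- "mapq"
  }
  len <- dt$end - dt$start
  badlen <- is.na(reason) & (len < min_len | len > max_len)
  reason[badlen] <- "length"

  if (!is.null(blacklist)) {
    bl <- .read_bed3(blacklist)
    if (nrow(bl)) {
      cand <- which(is.na(reason))
      if (length(cand)) {
        frag_gr <- GenomicRanges::GRanges(
          dt$chrom[cand], IRanges::IRanges(dt$start[cand] + 1L, dt$end[cand]))
        bl_gr <- GenomicRanges::GRanges(
          bl$chrom, IRanges::IRanges(bl$start + 1L, bl$end))
        hit <- IRanges::overlapsAny(frag_gr, bl_gr)
        reason[cand[hit]] <- "blacklist"
      }
    }
  }

  tab <- table(factor(reason, levels = names(log)))
  log[names(tab)] <- as.integer(tab)
  kept <- dt[is.na(reason)]
  structure(list(fragments = kept,
                 log = c(as.list(log),
                         list(n_in = n_in, n_kept = nrow(kept),
                              mapq_checked = has_mapq))),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set:", nrow(x$fragments), "fragments kept of",
      x$log$n_in, "input records\n")
  invisible(x)
}

.as_fragment_table <- function(fragments) {
  if (inherits(fragments, "fragment_set")) return(fragments$fragments)
  data.table::as.data.table(fragments)
}

#' Randomly downsample a fragment set
#'
#' Keeps each fragment independently with probability `fraction`
#' (Bernoulli thinning), the standard way to emulate lower sequencing depth.
#' Deterministic for a fixed seed.
#'
#' @param fragments A `fragment_set` or fragment data.table.
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer seed.
#' @return Object of the same kind as the input, thinned.
#' @export
downsample_fragments <- function(fragments, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  dt <- .as_fragment_table(fragments)
  if (fraction == 1) keep <- rep(TRUE, nrow(dt)) else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    keep <- stats::runif(nrow(dt)) < fraction
  }
  out <- dt[keep]
  if (inherits(fragments, "fragment_set")) {
    structure(list(fragments = out,
                   log = utils::modifyList(fragments$log,
                                           list(n_kept = nrow(out),
                                                downsample_fraction = fraction))),
              class = "fragment_set")
  } else out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
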