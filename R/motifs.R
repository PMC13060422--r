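#' k-mer motif lexicon
#'
#' Lexicographically ordered k-mers over the DNA alphabet A, C, G, T. Column
#' order of every motif count matrix in the package follows this lexicon, so
#' motif `i` of a k=4 matrix is `motif_lexicon(4)[i]` (256 entries for k=4).
#'
#' @param k Motif length (integer, 1--8).
#' @return Character vector of length `4^k`, lexicographic order.
#' @export
#' @examples
#' head(motif_lexicon(2))  # "AA" "AC" "AG" "AT" "CA" "CC"
motif_lexicon <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 1L, k <= 8L, k == round(k))
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; reverse for lexicographic
  do.call(paste0, rev(grid))
}

# Integer base codes along a sequence string: A=0, C=1, G=2, T=3, else NA.
.base_codes <- local({
  tab <- rep(NA_integer_, 256L)
  tab[utf8ToInt("A")] <- 0L; tab[utf8ToInt("C")] <- 1L
  tab[utf8ToInt("G")] <- 2L; tab[utf8ToInt("T")] <- 3L
  tab[utf8ToInt("a")] <- 0L; tab[utf8ToInt("c")] <- 1L
  tab[utf8ToInt("g")] <- 2L; tab[utf8ToInt("t")] <- 3L
  tab
})

.seq_codes <- function(seq_string) {
  .base_codes[utf8ToInt(seq_string)]
}

# 1-based vector v with v[p] = 0-based lexicon index of the k-mer starting at
# 0-based position p-1, NA where the window contains a non-ACGT base or runs
# off the end.
.kmer_index_track <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer(0L))
  m <- n - k + 1L
  idx <- integer(m)
  for (j in seq_len(k)) {
    idx <- idx + codes[j:(m + j - 1L)] * 4L^(k - j)
  }
  idx
}

# Reverse-complement permutation of 0-based k-mer indices: rc[i+1] is the
# index of revcomp(motif i).
.revcomp_index <- function(k) {
  idx <- 0:(4L^k - 1L)
  rc <- integer(length(idx))
  rem <- idx
  for (j in seq_len(k)) {
    digit <- rem %% 4L           # j-th base from the 3' side
    rc <- rc + (3L - digit) * 4L^(k - j)
    rem <- rem %/% 4L
  }
  rc
}

# Reverse complement of plain character k-mers (no external dependency so it
# can double as a slow-path check in tests).
.revcomp_chr <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L))
}
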