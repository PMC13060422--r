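# Shared desk-scale fixtures, built once per test run and memoized.
.fixture_env <- new.env(parent = emptyenv())

# 1 x 1 Mb toy reference with a 100 kb layout (10 bins)
tiny_genome <- function() {
  if (is.null(.fixture_env$tiny)) {
    ref <- make_toy_reference(1, 1e6, seed = 42,
                              dir = file.path(tempdir(), "tiny_ref"))
    layout <- load_layout(ref$chrom_sizes, bin_size = 1e5)
    .fixture_env$tiny <- list(ref = ref, layout = layout,
                              seq = .rmds_ref_seq(ref$fasta))
  }
  .fixture_env$tiny
}

# 2 x 5 Mb toy reference with a 100 kb layout (100 bins)
toy_genome <- function() {
  if (is.null(.fixture_env$toy)) {
    ref <- make_toy_reference(2, 5e6, seed = 7,
                              dir = file.path(tempdir(), "toy_ref"))
    layout <- load_layout(ref$chrom_sizes, bin_size = 1e5)
    .fixture_env$toy <- list(ref = ref, layout = layout)
  }
  .fixture_env$toy
}

.rmds_ref_seq <- function(fasta) {
  ss <- Biostrings::readDNAStringSet(fasta)
  names(ss) <- sub("\\s.*$", "", names(ss))
  setNames(toupper(as.character(ss)), names(ss))
}

# slow-path reverse complement for oracles
rc_oracle <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# brute-force per-fragment end-motif counting oracle (character arithmetic
# only, independent of the package's integer-track implementation)
oracle_end_motifs <- function(frags, seqs, layout, k = 4,
                              end_side = "five_prime") {
  lex <- motif_lexicon(k)
  n_bins <- nrow(layout$bins)
  counts <- matrix(0L, n_bins, 4^k, dimnames = list(layout$bins$bin_id, lex))
  edge <- 0L; disc <- 0L; masked <- 0L
  for (i in seq_len(nrow(frags))) {
    ch <- frags$chrom[i]; s <- frags$start[i]; e <- frags$end[i]
    L <- nchar(seqs[[ch]])
    for (side in c("up", "dn")) {
      if (side == "up") {
        if (s + k > L || s < 0) { edge <- edge + 1L; next }
        mot <- substr(seqs[[ch]], s + 1, s + k)
        if (end_side == "three_prime") mot <- rc_oracle(mot)
        pos <- s
      } else {
        if (e - k < 0 || e > L) { edge <- edge + 1L; next }
        mot <- substr(seqs[[ch]], e - k + 1, e)
        if (end_side == "five_prime") mot <- rc_oracle(mot)
        pos <- e - 1
      }
      if (!mot %in% lex) { disc <- disc + 1L; next }
      b <- which(layout$bins$chrom == ch & layout$bins$start <= pos &
                   layout$bins$end > pos)
      if (!length(b) || !layout$bins$usable[b]) { masked <- masked + 1L; next }
      counts[b, mot] <- counts[b, mot] + 1L
    }
  }
  list(counts = counts, edge = edge, disc = disc, masked = masked)
}

# independent entropy oracle (base-2 logs, explicit loop)
oracle_rmds <- function(counts) {
  tot <- sum(counts)
  h <- 0
  for (c_i in counts) {
    if (c_i > 0) {
      p <- c_i / tot
      h <- h - p * log2(p)
    }
  }
  h / log2(length(counts))
}
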