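#' Simulation configuration for synthetic cfDNA cohorts
#'
#' Collects the knobs of the fragment-level cohort simulator. Defaults are the
#' package's desk-scale study conditions: a 2 x 5 Mb toy genome in 100 kb bins
#' with 4-mer motifs, three institutes, three ordered timepoints, and a
#' planted entropy deficit (`effect_delta < 1`) in non-responders at the
#' effect bins.
#'
#' @param n_chromosomes,chrom_length Toy genome shape.
#' @param bin_size Bin width in bp.
#' @param k Motif length.
#' @param n_patients_per_group Patients per response group.
#' @param institutes Institute labels; patients are assigned round-robin so
#'   both groups appear at every institute.
#' @param timepoints Ordered timepoint labels (least to most recent).
#' @param coverage Mean fragments per bin per sample (Poisson).
#' @param base_concentration Symmetric Dirichlet concentration per motif;
#'   larger values give more uniform (higher-entropy) motif usage.
#' @param bin_variation_sd SD of the per-bin log-scale baseline motif tilt,
#'   drawn once per cohort and shared by all samples; gives each bin a stable
#'   motif landscape so profiles correlate across depths.
#' @param effect_bins Bin ids (in the layout) carrying the response effect.
#' @param effect_delta Concentration multiplier applied to non-responders at
#'   effect bins; < 1 lowers their regional entropy, > 1 raises it.
#' @param batch_tilt_sd SD of per-(institute, library date) log-scale motif
#'   perturbations.
#' @param trajectory_pattern Per-effect-bin label in
#'   `c("cluster1", "cluster2", "cluster3")` (recycled): cluster1 = effect at
#'   Screen and the last timepoint but not in between; cluster2 = constant
#'   effect; cluster3 = constant effect of opposite sign.
#' @param fraglen_mean,fraglen_sd Fragment length distribution in bp
#'   (truncated to 50--350).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2L, chrom_length = 5e6L,
                       bin_size = 100000L, k = 4L,
                       n_patients_per_group = 6L,
                       institutes = c("instA", "instB", "instC"),
                       timepoints = c("Screen", "Day0", "AdjWk1"),
                       coverage = 300,
                       base_concentration = 5,
                       bin_variation_sd = 0.3,
                       effect_bins = integer(0L),
                       effect_delta = 0.5,
                       batch_tilt_sd = 0.05,
                       trajectory_pattern = "cluster2",
                       fraglen_mean = 166, fraglen_sd = 20,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              bin_size = as.integer(bin_size), k = as.integer(k),
              n_patients_per_group = as.integer(n_patients_per_group),
              institutes = institutes, timepoints = timepoints,
              coverage = coverage,
              base_concentration = base_concentration,
              bin_variation_sd = bin_variation_sd,
              effect_bins = as.integer(effect_bins),
              effect_delta = effect_delta,
              batch_tilt_sd = batch_tilt_sd,
              trajectory_pattern = trajectory_pattern,
              fraglen_mean = fraglen_mean, fraglen_sd = fraglen_sd,
              seed = as.integer(seed))
  stopifnot(cfg$coverage > 0, cfg$base_concentration > 0,
            length(cfg$timepoints) >= 1L, cfg$effect_delta > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Write a toy reference genome
#'
#' I.i.d. uniform A/C/G/T chromosomes plus a matching chrom.sizes table and
#' a samtools-style FASTA index. Deterministic for a fixed seed.
#'
#' @param n_chromosomes,chrom_length Genome shape.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param prefix File name stem.
#' @return List with `fasta`, `chrom_sizes` paths and the `sizes` table.
#' @export
make_toy_reference <- function(n_chromosomes = 2L, chrom_length = 5e6L,
                               seed = 1L, dir = tempfile("toyref"),
                               prefix = "toy") {
  if (chrom_length <= 0) stop("chrom_length must be positive")
  if (n_chromosomes <= 0) stop("n_chromosomes must be positive")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chromosomes))
  seqs <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
          collapse = "")
  }, character(1L))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- chroms
  fa <- file.path(dir, paste0(prefix, ".fa"))
  Biostrings::writeXStringSet(ss, fa)
  Rsamtools::indexFa(fa)
  sizes <- data.table::data.table(chrom = chroms, length = chrom_length)
  cs <- file.path(dir, paste0(prefix, ".chrom.sizes"))
  data.table::fwrite(sizes, cs, sep = "\t", col.names = FALSE)
  list(fasta = fa, chrom_sizes = cs, sizes = sizes)
}

# trajectory weight of the planted effect at each timepoint index
.trajectory_weights <- function(pattern, n_timepoints) {
  w <- switch(pattern,
    cluster1 = { v <- rep(1, n_timepoints); if (n_timepoints > 2)
                   v[2:(n_timepoints - 1)] <- 0; v },
    cluster2 = rep(1, n_timepoints),
    cluster3 = rep(-1, n_timepoints),
    stop("unknown trajectory pattern: ", pattern))
  w
}

# per-chromosome indexes used by the placement sampler
.build_placement_index <- function(seq_string, k, bin_size) {
  codes <- .seq_codes(seq_string)
  track <- .kmer_index_track(codes, k)          # 0-based pos p -> track[p+1]
  rc <- .revcomp_index(k)
  L <- length(codes)
  p0 <- 0:(L - k)
  n_motifs <- 4L^k

  # upstream pools grouped by (local bin, motif)
  key <- (p0 %/% bin_size) * n_motifs + track
  o <- order(key, p0)
  up_pos <- p0[o]; up_key <- key[o]
  brk <- c(1L, which(diff(up_key) != 0L) + 1L)
  up_keys <- up_key[brk]
  up_lo <- brk
  up_hi <- c(brk[-1L] - 1L, length(up_key))

  # downstream positions grouped by five_prime downstream motif
  e0 <- p0 + k                                   # candidate fragment ends
  dmot <- rc[track + 1L]
  o2 <- order(dmot, e0)
  dn_pos <- e0[o2]; dn_mot <- dmot[o2]
  brk2 <- c(1L, which(diff(dn_mot) != 0L) + 1L)
  dn_keys <- dn_mot[brk2]
  dn_lo <- brk2
  dn_hi <- c(brk2[-1L] - 1L, length(dn_mot))

  list(L = L, n_motifs = n_motifs,
       up_pos = up_pos, up_keys = up_keys, up_lo = up_lo, up_hi = up_hi,
       dn_pos = dn_pos, dn_keys = dn_keys, dn_lo = dn_lo, dn_hi = dn_hi)
}

.pool_lookup <- function(keys, key) {
  j <- findInterval(key, keys)
  ok <- j >= 1L & keys[pmax(j, 1L)] == key
  j[!ok] <- NA_integer_
  j
}

#' Simulate a longitudinal multi-institute fragment cohort
#'
#' Writes one BED fragment file per sample plus a metadata TSV and a
#' ground-truth JSON. Fragment start positions are drawn within bins; each
#' fragment's 5' end motifs are realized against the toy reference: the
#' upstream end is placed at a reference position whose k-mer equals a motif
#' drawn from the bin's Dirichlet-multinomial motif distribution, and the
#' downstream end is matched to its drawn motif by nearest-position search
#' within the 50--350 bp length window (falling back to the uncontrolled
#' position at the target length when the motif is absent in-window, tallied
#' in the truth object). Motif extraction therefore has to read the
#' reference to recover the planted distributions.
#'
#' The per-bin concentration vector is
#' `base_concentration * bin_tilt * batch_tilt`, times `effect_delta`
#' raised to the trajectory weight for non-responders at effect bins.
#'
#' @param config A [sim_config()].
#' @param layout A `genome_layout` built at `config$bin_size` on the toy
#'   genome.
#' @param reference FASTA path or named sequences (from
#'   [make_toy_reference()]).
#' @param dir Output directory.
#' @return List with `fragment_files` (named by sample), `metadata_file`,
#'   `truth_file`, `metadata` (data.table) and `truth` (list).
#' @export
simulate_cohort <- function(config, layout, reference,
                            dir = tempfile("cohort")) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "genome_layout"))
  if (length(config$effect_bins) &&
      !all(config$effect_bins %in% layout$bins$bin_id)) {
    stop("effect_bins outside layout")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- .load_reference(reference)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n_motifs <- 4L^config$k
  tps <- config$timepoints
  n_tp <- length(tps)
  npg <- config$n_patients_per_group

  patients <- data.table::data.table(
    patient_id = sprintf("P%03d", seq_len(2L * npg)),
    response = rep(c("Responder", "Non-Responder"), each = npg))
  patients[, institute := config$institutes[
    ((seq_len(.N) - 1L) %% length(config$institutes)) + 1L]]

  iso_dates <- paste0("iso_", sprintf("%02d", 1:3))
  lib_dates <- paste0("lib_", sprintf("%02d", 1:3))
  meta <- data.table::CJ(patient_id = patients$patient_id, timepoint = tps,
                         sorted = FALSE)
  meta <- merge(meta, patients, by = "patient_id", sort = FALSE)
  data.table::setorder(meta, patient_id, timepoint)
  meta[, sample_id := paste(patient_id, timepoint, sep = "_")]
  meta[, isolation_date := sample(iso_dates, .N, replace = TRUE)]
  meta[, library_date := sample(lib_dates, .N, replace = TRUE)]
  pat_cov <- data.table::data.table(
    patient_id = patients$patient_id,
    age = round(stats::rnorm(nrow(patients), 60, 8)),
    gender = sample(c("M", "F"), nrow(patients), replace = TRUE),
    smoking = sample(c("never", "former", "current"), nrow(patients),
                     replace = TRUE),
    alcohol = sample(c("no", "yes"), nrow(patients), replace = TRUE))
  meta <- merge(meta, pat_cov, by = "patient_id", sort = FALSE)
  data.table::setcolorder(meta, c("sample_id", "patient_id", "institute",
                                  "timepoint", "isolation_date",
                                  "library_date", "response", "age",
                                  "gender", "smoking", "alcohol"))

  # stable per-bin baseline motif tilt (shared by every sample)
  n_bins <- nrow(layout$bins)
  bin_tilt <- matrix(exp(stats::rnorm(n_bins * n_motifs, 0,
                                      config$bin_variation_sd)),
                     nrow = n_bins)

  # batch tilt per observed (institute, library_date) combination
  batches <- unique(meta[, .(institute, library_date)])
  data.table::setorder(batches, institute, library_date)
  batch_tilt <- lapply(seq_len(nrow(batches)), function(i) {
    exp(stats::rnorm(n_motifs, 0, config$batch_tilt_sd))
  })
  names(batch_tilt) <- paste(batches$institute, batches$library_date,
                             sep = "|")

  patt <- rep_len(config$trajectory_pattern,
                  max(length(config$effect_bins), 1L))
  traj_w <- lapply(patt, .trajectory_weights, n_timepoints = n_tp)

  # effect multiplier on the concentration for (bin, timepoint) in NR samples
  delta_mat <- matrix(1, nrow = n_bins, ncol = n_tp)
  for (i in seq_along(config$effect_bins)) {
    delta_mat[config$effect_bins[i], ] <- config$effect_delta^traj_w[[i]]
  }

  chroms <- names(layout$chroms)
  pidx <- lapply(chroms, function(ch)
    .build_placement_index(seqs[[ch]], config$k, layout$bin_size))
  names(pidx) <- chroms
  chrom_bins <- split(seq_len(n_bins), layout$bins$chrom)[chroms]

  frag_files <- character(nrow(meta))
  names(frag_files) <- meta$sample_id
  n_fallback <- 0L

  for (si in seq_len(nrow(meta))) {
    srow <- meta[si]
    is_nr <- srow$response == "Non-Responder"
    ti <- match(srow$timepoint, tps)
    tilt <- batch_tilt[[paste(srow$institute, srow$library_date, sep = "|")]]
    parts <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]; px <- pidx[[ch]]
      rows <- chrom_bins[[ch]]
      frag_list <- vector("list", length(rows))
      for (bi in seq_along(rows)) {
        b <- rows[bi]
        if (!layout$bins$usable[b]) next
        nf <- stats::rpois(1L, config$coverage)
        if (nf == 0L) next
        alpha <- config$base_concentration * bin_tilt[b, ] * tilt
        if (is_nr) alpha <- alpha * delta_mat[b, ti]
        p <- stats::rgamma(n_motifs, shape = alpha)
        p <- p / sum(p)
        up_counts <- stats::rmultinom(1L, nf, p)[, 1L]
        local_lo <- layout$bins$start[b]
        starts <- integer(nf); fill <- 0L
        local_bin <- local_lo %/% layout$bin_size
        for (m in which(up_counts > 0L)) {
          c_m <- up_counts[m]
          j <- .pool_lookup(px$up_keys,
                            local_bin * n_motifs + (m - 1L))
          if (is.na(j)) {           # motif absent in bin: uniform fallback
            pos <- local_lo + sample.int(layout$bins$end[b] - local_lo,
                                         c_m, replace = TRUE) - 1L
            n_fallback <- n_fallback + c_m
          } else {
            pool <- px$up_pos[px$up_lo[j]:px$up_hi[j]]
            pos <- pool[sample.int(length(pool), c_m, replace = TRUE)]
          }
          starts[(fill + 1L):(fill + c_m)] <- pos
          fill <- fill + c_m
        }
        lens <- pmin(pmax(round(stats::rnorm(nf, config$fraglen_mean,
                                             config$fraglen_sd)), 50L), 350L)
        dn_m <- sample.int(n_motifs, nf, replace = TRUE, prob = p)
        frag_list[[bi]] <- data.table::data.table(
          start = starts, target = starts + lens, dn_m = dn_m)
      }
      fr <- data.table::rbindlist(frag_list)
      if (!nrow(fr)) next
      # match fragment ends to the drawn downstream motifs
      ends <- pmin(fr$target, px$L)
      for (m in unique(fr$dn_m)) {
        idx <- which(fr$dn_m == m)
        j <- .pool_lookup(px$dn_keys, m - 1L)
        if (is.na(j)) { n_fallback <- n_fallback + length(idx); next }
        v <- px$dn_pos[px$dn_lo[j]:px$dn_hi[j]]
        s <- fr$start[idx]; tg <- fr$target[idx]
        lo <- findInterval(s + 49L, v) + 1L
        hi <- findInterval(s + 350L, v)
        jj <- pmin(pmax(findInterval(tg, v), lo), hi)
        j2 <- pmin(jj + 1L, hi)
        has <- lo <= hi
        pick <- ifelse(has & abs(v[pmax(j2, 1L)] - tg) <
                         abs(v[pmax(jj, 1L)] - tg), j2, jj)
        e <- ifelse(has, v[pmax(pick, 1L)], pmin(tg, px$L))
        n_fallback <- n_fallback + sum(!has)
        ends[idx] <- e
      }
      parts[[ci]] <- data.table::data.table(
        chrom = ch, start = fr$start, end = ends)
    }
    frags <- data.table::rbindlist(parts)
    data.table::setorder(frags, chrom, start, end)
    frags[, `:=`(name = paste0(srow$sample_id, "_f", seq_len(.N)),
                 mapq = 60L, strand = "+")]
    f <- file.path(dir, paste0(srow$sample_id, ".bed"))
    data.table::fwrite(frags, f, sep = "\t", col.names = FALSE)
    frag_files[srow$sample_id] <- f
  }

  meta_file <- file.path(dir, "metadata.tsv")
  data.table::fwrite(meta, meta_file, sep = "\t")

  truth <- list(
    config = unclass(config),
    bin_tilt = bin_tilt,
    batch_tilt = batch_tilt,
    delta_by_timepoint = delta_mat[config$effect_bins, , drop = FALSE],
    effect_bins = config$effect_bins,
    trajectory_pattern = patt,
    expected_p_baseline = bin_tilt / rowSums(bin_tilt),
    n_fallback = n_fallback)
  truth_file <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA)

  list(fragment_files = frag_files, metadata_file = meta_file,
       truth_file = truth_file, metadata = meta, truth = truth)
}

#' Simulate a Z-rMDS matrix cohort directly
#'
#' Matrix-level companion to [simulate_cohort()]: generates a samples x bins
#' matrix on the Z-rMDS scale without fragment placement, for studies whose
#' bin counts exceed what a toy fragment-level genome provides (batch
#' correction, differential testing, and classification calibrations use
#' thousands of bins). The generative model per sample s and bin b is
#' \deqn{y_{sb} = effect(b, group_s, timepoint_s) + u_{patient(s)} +
#'   inst_{institute(s)} + tilt_{institute(s), b} + e_{sb}}
#' with patient-by-bin random effects sized to the requested intra-patient
#' correlation (`u_pb ~ N(0, icc)` independent across bins but shared by a
#' patient's timepoints, `e ~ N(0, 1 - icc)`, so the total residual SD is 1
#' and `effect_size` is in residual-SD units). Patient effects are per bin,
#' not genome-wide: a Z-rMDS profile is centered within sample, so a global
#' per-patient shift cannot occur in the data this emulates — what persists
#' across a patient's timepoints is their regional profile. Non-responders
#' carry the planted effect at `effect_bins`, shaped over timepoints by the
#' same trajectory patterns as the fragment simulator.
#'
#' @param n_patients_per_group Patients per response group.
#' @param n_bins Number of genomic bins.
#' @param effect_bins Indices of bins carrying the response effect.
#' @param effect_size Effect in residual-SD units added to non-responders.
#' @param timepoints Ordered timepoint labels.
#' @param institutes Institute labels (round-robin patient assignment).
#' @param institute_offsets Optional named numeric: a constant offset per
#'   institute applied to every bin (planted batch effect).
#' @param batch_tilt_sd SD of per-(institute, bin) random offsets (a batch
#'   effect with a different direction per institute).
#' @param date_tilt_sd SD of per-(isolation date, library date, bin) random
#'   offsets; with 3 x 3 date combinations this plants a higher-rank batch
#'   structure than the institutes alone.
#' @param patient_icc Intra-patient correlation of the residuals in [0, 1).
#' @param trajectory_pattern Recycled over effect bins; see [sim_config()].
#' @param seed Integer seed.
#' @return List with `values` (samples x bins matrix, rownames = sample ids,
#'   colnames = `bin_<i>`), `metadata` (data.table as in
#'   [simulate_cohort()]), and `truth` (planted parameters).
#' @export
simulate_rmds_matrix <- function(n_patients_per_group = 20L, n_bins = 2000L,
                                 effect_bins = integer(0L), effect_size = 1,
                                 timepoints = c("Screen", "Day0", "AdjWk1"),
                                 institutes = c("instA", "instB", "instC"),
                                 institute_offsets = NULL,
                                 batch_tilt_sd = 0,
                                 date_tilt_sd = 0,
                                 patient_icc = 0.4,
                                 trajectory_pattern = "cluster2",
                                 seed = 1L) {
  stopifnot(patient_icc >= 0, patient_icc < 1,
            all(effect_bins >= 1), all(effect_bins <= n_bins))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  npg <- n_patients_per_group
  n_tp <- length(timepoints)
  patients <- data.table::data.table(
    patient_id = sprintf("P%03d", seq_len(2L * npg)),
    response = rep(c("Responder", "Non-Responder"), each = npg))
  patients[, institute := institutes[((seq_len(.N) - 1L) %%
                                        length(institutes)) + 1L]]
  meta <- data.table::CJ(patient_id = patients$patient_id,
                         timepoint = timepoints, sorted = FALSE)
  meta <- merge(meta, patients, by = "patient_id", sort = FALSE)
  data.table::setorder(meta, patient_id, timepoint)
  meta[, sample_id := paste(patient_id, timepoint, sep = "_")]
  meta[, isolation_date := sample(paste0("iso_", 1:3), .N, replace = TRUE)]
  meta[, library_date := sample(paste0("lib_", 1:3), .N, replace = TRUE)]
  pat_cov <- data.table::data.table(
    patient_id = patients$patient_id,
    age = round(stats::rnorm(nrow(patients), 60, 8)),
    gender = sample(c("M", "F"), nrow(patients), replace = TRUE),
    smoking = sample(c("never", "former", "current"), nrow(patients),
                     replace = TRUE),
    alcohol = sample(c("no", "yes"), nrow(patients), replace = TRUE))
  meta <- merge(meta, pat_cov, by = "patient_id", sort = FALSE)
  data.table::setcolorder(meta, c("sample_id", "patient_id", "institute",
                                  "timepoint", "isolation_date",
                                  "library_date", "response", "age",
                                  "gender", "smoking", "alcohol"))
  n <- nrow(meta)

  patt <- rep_len(trajectory_pattern, max(length(effect_bins), 1L))
  w_mat <- matrix(0, nrow = n_bins, ncol = n_tp)
  for (i in seq_along(effect_bins)) {
    w_mat[effect_bins[i], ] <- .trajectory_weights(patt[i], n_tp)
  }

  u <- matrix(stats::rnorm(nrow(patients) * n_bins, 0, sqrt(patient_icc)),
              nrow = nrow(patients),
              dimnames = list(patients$patient_id, NULL))
  inst_off <- stats::setNames(rep(0, length(institutes)), institutes)
  if (!is.null(institute_offsets)) {
    inst_off[names(institute_offsets)] <- institute_offsets
  }
  tilt <- matrix(0, nrow = length(institutes), ncol = n_bins,
                 dimnames = list(institutes, NULL))
  if (batch_tilt_sd > 0) {
    tilt[] <- stats::rnorm(length(institutes) * n_bins, 0, batch_tilt_sd)
  }

  y <- matrix(stats::rnorm(n * n_bins, 0, sqrt(1 - patient_icc)),
              nrow = n, ncol = n_bins,
              dimnames = list(meta$sample_id, paste0("bin_", seq_len(n_bins))))
  y <- y + u[meta$patient_id, , drop = FALSE]
  y <- y + inst_off[meta$institute]
  y <- y + tilt[meta$institute, , drop = FALSE]
  if (date_tilt_sd > 0) {
    combo <- paste(meta$isolation_date, meta$library_date, sep = "|")
    combos <- sort(unique(combo))
    dtilt <- matrix(stats::rnorm(length(combos) * n_bins, 0, date_tilt_sd),
                    nrow = length(combos), dimnames = list(combos, NULL))
    y <- y + dtilt[combo, , drop = FALSE]
  }
  ti <- match(meta$timepoint, timepoints)
  nr <- meta$response == "Non-Responder"
  if (length(effect_bins)) {
    y[nr, ] <- y[nr, , drop = FALSE] +
      effect_size * t(w_mat[, ti[nr], drop = FALSE])
  }

  list(values = y, metadata = meta,
       truth = list(effect_bins = effect_bins, effect_size = effect_size,
                    trajectory_pattern = patt,
                    institute_offsets = inst_off, patient_icc = patient_icc,
                    patient_intercepts = u, trajectory_weights = w_mat))
}
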