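#' Read a flat key=value run configuration
#'
#' Lines of `key = value` (or `key: value`); `#` comments and blank lines
#' ignored. Values are parsed as numbers when possible, comma-separated
#' values become vectors.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("bad config line: ", ln)
    key <- trimws(m[2L]); val <- trimws(m[3L])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (!anyNA(num)) num else parts
  }
  cfg
}

.stage_log <- function(dir, stage, files, seed, config_hash) {
  info <- lapply(files, function(f) {
    list(path = basename(f), md5 = unname(tools::md5sum(f)))
  })
  entry <- list(stage = stage, version = as.character(
    utils::packageVersion("rmdskit")), seed = seed,
    config_hash = config_hash, files = info)
  log_file <- file.path(dir, "manifest.json")
  existing <- if (file.exists(log_file)) {
    jsonlite::read_json(log_file)
  } else list()
  existing[[stage]] <- entry
  jsonlite::write_json(existing, log_file, auto_unbox = TRUE, digits = NA)
  invisible(entry)
}

#' Run the full rMDS analysis pipeline on a simulated cohort
#'
#' End-to-end driver over the package's stages: cohort simulation (or
#' user-supplied fragment files), QC filtering, per-sample end-motif
#' extraction and rMDS/Z-rMDS profiles, matrix assembly, batch correction
#' with response preserved, standardization, moderated differential
#' testing, trajectory clustering of significant bins, telomere-proximity
#' enrichment, and patient-grouped classification. Every stage writes its
#' artifact to `out_dir` and is content-hashed into `manifest.json`
#' together with the package version, seed and config hash, so a rerun with
#' identical inputs reproduces identical hashes for the deterministic
#' stages.
#'
#' @param config Named list (or path read by [read_run_config()]) with any
#'   of: seed, bin_size, k, min_ends, q_threshold, n_components,
#'   n_chromosomes, chrom_length, coverage, n_patients_per_group,
#'   effect_bins (count), effect_delta, folds, rounds, n_null, n_perm.
#' @param out_dir Output directory.
#' @return Named list of stage results (invisibly writes artifacts).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("rmds_run")) {
  if (is.character(config)) config <- read_run_config(config)
  defaults <- list(seed = 1, bin_size = 1e5, k = 4, min_ends = 100,
                   q_threshold = 0.1, n_components = 6,
                   n_chromosomes = 2, chrom_length = 2e6, coverage = 250,
                   n_patients_per_group = 4, effect_bins = 6,
                   effect_delta = 0.4, folds = 4, rounds = 3,
                   n_null = 10000, n_perm = 10000)
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  seed <- as.integer(cfg$seed)

  ref <- make_toy_reference(cfg$n_chromosomes, cfg$chrom_length,
                            seed = seed, dir = file.path(out_dir, "ref"))
  layout <- load_layout(ref$chrom_sizes, bin_size = cfg$bin_size)
  n_bins <- nrow(layout$bins)
  eff <- seq_len(min(cfg$effect_bins, n_bins))
  sc <- sim_config(n_chromosomes = cfg$n_chromosomes,
                   chrom_length = cfg$chrom_length,
                   bin_size = cfg$bin_size, k = cfg$k,
                   n_patients_per_group = cfg$n_patients_per_group,
                   coverage = cfg$coverage, effect_bins = eff,
                   effect_delta = cfg$effect_delta, seed = seed)
  cohort <- simulate_cohort(sc, layout, ref$fasta,
                            dir = file.path(out_dir, "fragments"))
  .stage_log(out_dir, "simulate",
             c(cohort$metadata_file, cohort$truth_file), seed, cfg_hash)

  profiles <- list()
  for (sid in names(cohort$fragment_files)) {
    raw <- read_fragments(cohort$fragment_files[[sid]])
    fs <- filter_fragments(raw, layout)
    mc <- extract_end_motifs(fs, ref$fasta, layout, k = cfg$k,
                             sample_id = sid)
    profiles[[sid]] <- zscore_transform(
      rmds_from_counts(mc, min_ends = cfg$min_ends, layout = layout))
  }
  mat <- do.call(rbind, lapply(profiles, function(p) p$profile$z_rmds))
  colnames(mat) <- paste0("bin_", profiles[[1L]]$profile$bin_id)
  keep <- colSums(is.na(mat)) == 0L
  mat <- mat[, keep, drop = FALSE]
  mat_file <- file.path(out_dir, "zrmds_matrix.tsv")
  data.table::fwrite(data.table::data.table(sample_id = rownames(mat), mat),
                     mat_file, sep = "\t")
  .stage_log(out_dir, "rmds", mat_file, seed, cfg_hash)

  md <- cohort$metadata
  cm <- fit_correction(mat, md, batch_factors = "institute")
  corrected <- apply_correction(mat, md, cm)
  std <- standardize_bins(corrected)
  std_file <- file.path(out_dir, "corrected_matrix.tsv")
  data.table::fwrite(
    data.table::data.table(sample_id = rownames(std), std),
    std_file, sep = "\t")
  .stage_log(out_dir, "correct", std_file, seed, cfg_hash)

  diff_tab <- fit_differential(std, md,
                               covariates = c("age", "gender"))
  diff_file <- file.path(out_dir, "differential.tsv")
  data.table::fwrite(diff_tab, diff_file, sep = "\t")
  .stage_log(out_dir, "differential", diff_file, seed, cfg_hash)

  sig <- diff_tab$bin[!is.na(diff_tab$q) & diff_tab$q < cfg$q_threshold]
  res <- list(layout = layout, cohort = cohort, matrix = mat,
              corrected = std, differential = diff_tab,
              significant_bins = sig)

  if (length(sig) >= 3L) {
    cl <- cluster_bins(std, md, sig, n_clusters = min(3L, length(sig)))
    cl_file <- file.path(out_dir, "clusters.tsv")
    data.table::fwrite(cl, cl_file, sep = "\t")
    traj <- trajectory_summary(std, cl, md)
    enr <- lapply(split(cl$bin, cl$cluster), function(b) {
      ids <- as.integer(sub("bin_", "", b))
      if (length(ids) < 2L) return(NULL)
      telomere_enrichment(ids, layout, n_null = cfg$n_null,
                          n_perm = cfg$n_perm, seed = seed)
    })
    enr_file <- file.path(out_dir, "telomere_enrichment.json")
    jsonlite::write_json(
      lapply(enr, function(e) if (is.null(e)) NULL else
        list(n_bins = length(e$bin_ids), mw_p = e$mw_p,
             perm_p = e$perm_p, direction = e$direction)),
      enr_file, auto_unbox = TRUE, digits = NA)
    .stage_log(out_dir, "regions", c(cl_file, enr_file), seed, cfg_hash)
    res$clusters <- cl; res$trajectories <- traj; res$enrichment <- enr
  }

  scheme <- eval_scheme("repeated_kfold", folds = cfg$folds,
                        rounds = cfg$rounds)
  report <- run_evaluation(std, md, scheme,
                           n_components = cfg$n_components, seed = seed)
  rep_file <- file.path(out_dir, "classification.tsv")
  data.table::fwrite(report$aggregate, rep_file, sep = "\t")
  .stage_log(out_dir, "classify", rep_file, seed, cfg_hash)
  res$classification <- report
  invisible(res)
}
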