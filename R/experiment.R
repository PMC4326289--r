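#' Enumerate the eight simulation profiles
#'
#' The full cross of mutation rate (0, 0.01), read length (50, 100) and
#' sequencing error rate (0.0001, 0.01), named on the
#' `m{L,H}.len{050,100}.e{L,H}` grammar.
#'
#' @return data frame with `name`, `mutation_rate`, `read_length`,
#'   `error_rate` (8 rows).
#' @export
enumerate_profiles <- function() {
  grid <- expand.grid(e = c("L", "H"), len = c("050", "100"), m = c("L", "H"),
                      stringsAsFactors = FALSE)
  name <- sprintf("m%s.len%s.e%s", grid$m, grid$len, grid$e)
  data.frame(name = name,
             mutation_rate = ifelse(grid$m == "H", 0.01, 0),
             read_length = as.integer(grid$len),
             error_rate = ifelse(grid$e == "H", 0.01, 0.0001),
             stringsAsFactors = FALSE)
}

#' Enumerate the full simulated-dataset grid
#'
#' Crosses the 8 profiles with the two mixing ratios (9:1 and 1:1) and the
#' two region modes (exome-only or whole genome): 32 dataset configurations.
#'
#' @param profiles profile table from [enumerate_profiles()].
#' @return data frame with one row per dataset configuration.
#' @export
enumerate_datasets <- function(profiles = enumerate_profiles()) {
  grid <- expand.grid(profile = profiles$name, ratio = c("9:1", "1:1"),
                      regions = c("exome", "all"), stringsAsFactors = FALSE)
  grid[order(grid$profile, grid$ratio, grid$regions), , drop = FALSE] -> grid
  rownames(grid) <- NULL
  grid
}

parse_ratio <- function(ratio) {
  if (is.character(ratio)) {
    parts <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2 || any(is.na(parts))) stop("ratio must look like '9:1'")
    parts
  } else {
    stopifnot(length(ratio) == 2)
    as.numeric(ratio)
  }
}

#' Study configuration
#'
#' Collects every knob of an end-to-end simulation run. The default surrogate
#' scale — a 500 kb host genome over 2 chromosomes with 50 genes covering
#' roughly 15% of bases, read depth 60x — keeps a full run in the minutes
#' range while leaving enough reads for stable FDR/FNR estimates; `scale`
#' shrinks the genome (and gene count) proportionally for quick sweeps.
#'
#' @param profile a profile name (see [enumerate_profiles()]).
#' @param regions `"all"` (reads from everywhere) or `"exome"` (reads from
#'   CDS intervals only; alignment is unrestricted either way).
#' @param ratio host:graft read ratio, `"9:1"`-style string or numeric pair.
#' @param total_depth fold-coverage of the host regions carried by the full
#'   mixture.
#' @param host_depth,graft_depth optional explicit effective depths
#'   overriding `total_depth`/`ratio` (used for the depth-scheme runs, e.g.
#'   60:60).
#' @param genome_length,n_chromosomes,n_genes,gc_fraction host surrogate
#'   parameters (before `scale`).
#' @param divergence a [divergence_spec()] (its seed is re-derived from
#'   `seed`).
#' @param strategies subset of `c("direct", "filtering", "combined")`.
#' @param baseline also run the no-contamination control (host-only reads,
#'   direct mapping) at the host's effective depth.
#' @param k seed k-mer size; `band` the extension band; `min_frac` the
#'   successfully-aligned score floor.
#' @param min_qual variant-quality cutoff (Phred, default 13).
#' @param min_depth minimum pileup depth for calling.
#' @param pos_tolerance positional slack for alignment scoring.
#' @param scale multiplies `genome_length` and `n_genes`.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `study_config`.
#' @export
study_config <- function(profile = "mH.len100.eL", regions = "all",
                         ratio = "1:1", total_depth = 60,
                         host_depth = NULL, graft_depth = NULL,
                         genome_length = 5e5, n_chromosomes = 2L,
                         n_genes = 50L, gc_fraction = 0.45,
                         divergence = divergence_spec(),
                         strategies = c("direct", "filtering", "combined"),
                         baseline = TRUE, k = 15L, band = 8L, min_frac = 0.6,
                         min_qual = 13, min_depth = 3L, pos_tolerance = 5L,
                         scale = 1, seed = 1L) {
  prof <- sim_profile(profile)
  r <- parse_ratio(ratio)
  cfg <- list(profile = prof, regions = match.arg(regions, c("all", "exome")),
              ratio = r,
              total_depth = total_depth, host_depth = host_depth,
              graft_depth = graft_depth,
              genome_length = round(genome_length * scale),
              n_chromosomes = as.integer(n_chromosomes),
              n_genes = max(1L, as.integer(round(n_genes * scale))),
              gc_fraction = gc_fraction, divergence = divergence,
              strategies = match.arg(strategies,
                                     c("direct", "filtering", "combined"),
                                     several.ok = TRUE),
              baseline = baseline, k = as.integer(k), band = as.integer(band),
              min_frac = min_frac, min_qual = min_qual,
              min_depth = as.integer(min_depth),
              pos_tolerance = as.integer(pos_tolerance), seed = as.integer(seed))
  class(cfg) <- "study_config"
  cfg
}

#' Depth schemes for the data-volume comparison
#'
#' The three effective host:graft depth schemes: 54x:6x (a 60x mixture at
#' 9:1), 30x:30x (60x at 1:1) and 60x:60x (doubled data at 1:1).
#'
#' @return data frame with `label`, `host_depth`, `graft_depth`.
#' @export
depth_schemes <- function() {
  data.frame(label = c("54x:6x", "30x:30x", "60x:60x"),
             host_depth = c(54, 30, 60), graft_depth = c(6, 30, 60),
             stringsAsFactors = FALSE)
}

#' Run a complete simulation study
#'
#' Forges the host/graft genome pair, mutates both references, simulates and
#' mixes reads, runs the requested handling strategies (plus the
#' no-contamination baseline), calls and filters SNVs, and scores accuracy
#' at the alignment, variant and non-synonymous-SNV levels against the
#' planted truth. Fully deterministic given the config seed.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, FASTA/BED/FASTQ/SAM/VCF
#'   and report tables are written there.
#' @param verbose print per-stage progress.
#' @return list with `report` (the accuracy table), `contamination`
#'   (per-strategy estimated graft fraction and the true fraction), `counts`
#'   (per-strategy partition sizes) and `truth`/`genomes` details.
#' @export
run_study <- function(config = study_config(), out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  prof <- config$profile
  s <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))

  say("forging genomes (%d bp x %d chromosomes)", config$genome_length,
      config$n_chromosomes)
  host_ref <- generate_ancestor(config$genome_length, config$n_chromosomes,
                                config$gc_fraction, seed = s + 1L,
                                name = "human")
  ann <- annotate_genes(host_ref, config$n_genes, seed = s + 2L)
  div <- config$divergence
  div$seed <- s + 3L
  dv <- diverge(host_ref, ann, div, name = "mouse")
  graft_ref <- dv$genome
  graft_exome <- lift_intervals(ann$exome, dv$maps, "ref2der")

  say("mutating sample genomes (rate %g)", prof$mutation_rate)
  mut_h <- mutate_genome(host_ref, prof$mutation_rate, seed = s + 4L)
  mut_g <- mutate_genome(graft_ref, prof$mutation_rate, seed = s + 5L)

  regions_h <- if (config$regions == "exome")
    lift_intervals(ann$exome, mut_h$maps, "ref2der") else "whole"
  regions_g <- if (config$regions == "exome")
    lift_intervals(graft_exome, mut_g$maps, "ref2der") else "whole"

  # read budget: the mixture carries total_depth-fold coverage of the host
  # regions; counts split by the mixing ratio (9:1 -> 54x + 6x effective)
  len_h <- if (config$regions == "exome") interval_total_length(ann$exome)
           else sum(genome_lengths(host_ref))
  len_g <- if (config$regions == "exome") interval_total_length(graft_exome)
           else sum(genome_lengths(graft_ref))
  host_frac <- config$ratio[1] / sum(config$ratio)
  if (!is.null(config$host_depth)) {
    d_host <- config$host_depth
    d_graft <- config$graft_depth %||% 0
    n_host <- round(d_host * len_h / prof$read_length)
    n_graft <- round(d_graft * len_h / prof$read_length)
    n_total <- n_host + n_graft
  } else {
    n_total <- round(config$total_depth * len_h / prof$read_length)
    n_host <- round(n_total * host_frac)
    n_graft <- n_total - n_host
  }
  say("simulating reads: %d host + %d graft (%d bp, error %g)",
      n_host, n_graft, prof$read_length, prof$error_rate)
  pool_h <- if (n_host > 0)
    simulate_reads(mut_h$genome, regions_h, prof$read_length, prof$error_rate,
                   depth = 1.1 * n_host * prof$read_length / max(1, len_h),
                   seed = s + 6L, coord_map = mut_h$maps)
  else empty_read_set()
  pool_g <- if (n_graft > 0)
    simulate_reads(mut_g$genome, regions_g, prof$read_length, prof$error_rate,
                   depth = 1.1 * n_graft * prof$read_length / max(1, len_g),
                   seed = s + 7L, coord_map = mut_g$maps)
  else empty_read_set()
  reads <- mix_reads(pool_h, pool_g, c(n_host, n_graft), n_total, seed = s + 8L)

  say("building indexes (k=%d)", config$k)
  scoring <- aln_scoring()
  idx_h <- build_index(host_ref, k = config$k)
  idx_m <- build_index(graft_ref, k = config$k)
  idx_c <- build_index(list(host_ref, graft_ref), k = config$k)

  results <- list()
  for (strat in config$strategies) {
    say("running strategy: %s", strat)
    results[[strat]] <- switch(strat,
      direct = run_direct(reads, idx_h, scoring, config$min_frac,
                          band = config$band),
      filtering = run_filtering(reads, idx_m, idx_h, scoring, config$min_frac,
                                band = config$band),
      combined = run_combined(reads, index = idx_c, human_name = "human",
                              scoring = scoring, min_frac = config$min_frac,
                              band = config$band))
  }
  baseline_reads <- NULL
  if (config$baseline) {
    say("running no-contamination baseline")
    d_base <- if (!is.null(config$host_depth)) config$host_depth
              else effective_depth(config$total_depth, host_frac)
    baseline_reads <- simulate_reads(mut_h$genome, regions_h, prof$read_length,
                                     prof$error_rate, depth = d_base,
                                     seed = s + 9L, coord_map = mut_h$maps)
    results[["no_contamination"]] <- run_direct(baseline_reads, idx_h, scoring,
                                                config$min_frac,
                                                band = config$band)
  }

  say("calling variants (QUAL >= %g)", config$min_qual)
  scored <- list()
  contam <- list()
  counts <- list()
  calls_by_strategy <- list()
  for (strat in names(results)) {
    res <- results[[strat]]
    rds <- if (strat == "no_contamination") baseline_reads else reads
    cols <- pileup(res$human, rds, host_ref)
    calls <- filter_calls(call_snvs(cols, config$min_depth), config$min_qual)
    calls_by_strategy[[strat]] <- calls
    scored[[strat]] <- list(
      score_alignments(res, config$pos_tolerance, host_name = "human"),
      score_variants(calls, mut_h$truth),
      score_nonsynonymous(calls, mut_h$truth, ann$genes, host_ref))
    counts[[strat]] <- data.frame(
      strategy = strat, human_aligned = nrow(res$human),
      mouse_aligned = nrow(res$mouse),
      unaligned = length(res$unaligned_ids), stringsAsFactors = FALSE)
    est <- if (nrow(res$mouse) + nrow(res$human) > 0 && strat != "direct" &&
               strat != "no_contamination")
      estimate_contamination(nrow(res$mouse), nrow(res$human)) else NA_real_
    contam[[strat]] <- data.frame(strategy = strat, estimated = est,
                                  true_fraction = n_graft / max(1, n_total),
                                  stringsAsFactors = FALSE)
  }
  report <- accuracy_report(scored)
  out <- list(report = report,
              contamination = do.call(rbind, contam),
              counts = do.call(rbind, counts),
              truth = mut_h$truth, annotations = ann,
              genomes = list(host = host_ref, graft = graft_ref),
              calls = calls_by_strategy,
              n_reads = c(host = n_host, graft = n_graft, total = n_total),
              config = config)
  if (!is.null(out_dir)) {
    read_sets <- lapply(names(results), function(strat)
      if (strat == "no_contamination") baseline_reads else reads)
    names(read_sets) <- names(results)
    write_study_artifacts(out, reads, read_sets, idx_c, results, out_dir)
  }
  out
}

write_study_artifacts <- function(study, reads, read_sets, idx_c, results,
                                  out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(study$genomes$host, file.path(out_dir, "host_ref.fasta"))
  write_genome_fasta(study$genomes$graft, file.path(out_dir, "graft_ref.fasta"))
  write_bed(study$annotations$exome, file.path(out_dir, "exome.bed"))
  write_gene_table(study$annotations$genes, file.path(out_dir, "genes.tsv"))
  write_fastq(reads, file.path(out_dir, "reads.fastq"))
  write_variant_truth(study$truth, file.path(out_dir, "truth_variants.tsv"))
  for (strat in names(results)) {
    # the combined index header covers both genomes' chromosomes
    export_strategy_result(results[[strat]], read_sets[[strat]], idx_c,
                           file.path(out_dir, strat))
    if (!is.null(study$calls[[strat]]))
      write_vcf(study$calls[[strat]],
                file.path(out_dir, paste0(strat, ".vcf")))
  }
  write.table(study$report, file.path(out_dir, "accuracy_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
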