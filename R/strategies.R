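#' Strategy result container
#'
#' The three read-handling strategies partition the input reads into three
#' sets: aligned to the host ("human") reference, aligned to the graft
#' ("mouse") reference (for the filtering strategy this is the discarded
#' set), and unaligned.
#'
#' @name strategy_result
#' @keywords internal
NULL

new_strategy_result <- function(strategy, human, mouse, unaligned_ids, n_reads) {
  stopifnot(nrow(human) + nrow(mouse) + length(unaligned_ids) == n_reads)
  structure(list(strategy = strategy, human = human, mouse = mouse,
                 unaligned_ids = unaligned_ids, n_reads = n_reads),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: %d human-aligned, %d mouse-aligned/discarded, %d unaligned (of %d)\n",
              x$strategy, nrow(x$human), nrow(x$mouse),
              length(x$unaligned_ids), x$n_reads))
  invisible(x)
}

#' Direct mapping strategy
#'
#' Aligns every read to the host (human) reference only; contaminating graft
#' reads that happen to align are retained, which is this strategy's
#' false-positive mechanism.
#'
#' @param reads a `read_set`.
#' @param human_index `seed_index` over the host reference only.
#' @param scoring an [aln_scoring()].
#' @param min_frac score floor for the successfully-aligned criterion.
#' @param ... passed to [align_reads()] (e.g. `band`).
#' @return a `strategy_result`.
#' @export
run_direct <- function(reads, human_index, scoring = aln_scoring(),
                       min_frac = 0.6, ...) {
  aln <- align_reads(reads, human_index, scoring = scoring, ...)
  ok <- is_aligned_ok(aln, scoring, min_frac)
  new_strategy_result("direct",
                      human = aln[ok, , drop = FALSE],
                      mouse = aln[0, , drop = FALSE],
                      unaligned_ids = aln$read_id[!ok],
                      n_reads = nrow(aln))
}

#' Filtering strategy
#'
#' Aligns all reads to the graft (mouse) reference first and discards those
#' that align successfully (optionally under a stricter score cutoff); the
#' remaining reads are then aligned to the host reference. Discarded reads
#' are retained in the result so the contamination fraction can still be
#' estimated from them.
#'
#' @param reads a `read_set`.
#' @param mouse_index,human_index single-genome `seed_index` objects.
#' @param scoring an [aln_scoring()].
#' @param min_frac score floor for the successfully-aligned criterion.
#' @param filter_min_score optional absolute score cutoff for the discard
#'   step (default: the same successfully-aligned criterion).
#' @param ... passed to [align_reads()].
#' @return a `strategy_result` (`mouse` holds the discarded reads).
#' @export
run_filtering <- function(reads, mouse_index, human_index,
                          scoring = aln_scoring(), min_frac = 0.6,
                          filter_min_score = NULL, ...) {
  m_aln <- align_reads(reads, mouse_index, scoring = scoring, ...)
  discard <- is_aligned_ok(m_aln, scoring, min_frac, min_score = filter_min_score)
  rest <- reads[!discard, , drop = FALSE]
  h_aln <- align_reads(rest, human_index, scoring = scoring, ...)
  ok <- is_aligned_ok(h_aln, scoring, min_frac)
  new_strategy_result("filtering",
                      human = h_aln[ok, , drop = FALSE],
                      mouse = m_aln[discard, , drop = FALSE],
                      unaligned_ids = h_aln$read_id[!ok],
                      n_reads = nrow(reads))
}

#' Combined-reference strategy
#'
#' Aligns each read once against a union index over both references and
#' assigns it to the genome holding its unique best-scoring locus. A read
#' whose best score is attained at more than one locus — in particular at
#' homologous loci of the two genomes — is left unaligned (the tie rule).
#'
#' @param reads a `read_set`.
#' @param index a `seed_index` over both genomes; alternatively supply
#'   `human_genome` and `mouse_genome` and the index is built here.
#' @param human_genome,mouse_genome `xeno_genome` objects (used when `index`
#'   is `NULL`).
#' @param human_name name of the host genome within the index.
#' @param scoring an [aln_scoring()].
#' @param min_frac score floor for the successfully-aligned criterion.
#' @param k k-mer size when the index is built here.
#' @param ... passed to [align_reads()].
#' @return a `strategy_result`.
#' @export
run_combined <- function(reads, index = NULL, human_genome = NULL,
                         mouse_genome = NULL, human_name = NULL,
                         scoring = aln_scoring(), min_frac = 0.6, k = 15L, ...) {
  if (is.null(index)) {
    stopifnot(!is.null(human_genome), !is.null(mouse_genome))
    index <- build_index(list(human_genome, mouse_genome), k = k)
    human_name <- human_name %||% human_genome$name
  }
  human_name <- human_name %||% index$genome_names[1]
  aln <- align_reads(reads, index, scoring = scoring, ...)
  ok <- is_aligned_ok(aln, scoring, min_frac)
  gname <- sub(":.*$", "", aln$ref_chrom)
  is_h <- ok & !is.na(gname) & gname == human_name
  is_m <- ok & !is.na(gname) & gname != human_name
  new_strategy_result("combined",
                      human = aln[is_h, , drop = FALSE],
                      mouse = aln[is_m, , drop = FALSE],
                      unaligned_ids = aln$read_id[!ok],
                      n_reads = nrow(aln))
}

#' Estimate the contamination fraction from alignment counts
#'
#' The number of reads aligned to the graft (mouse) reference as a fraction
#' of the number aligned to either reference.
#'
#' @param n_mouse_aligned,n_human_aligned non-negative read counts.
#' @return the fraction `n_mouse / (n_mouse + n_human)`; `NA` (with a
#'   warning) when both counts are zero.
#' @export
estimate_contamination <- function(n_mouse_aligned, n_human_aligned) {
  if (n_mouse_aligned < 0 || n_human_aligned < 0)
    stop("counts must be non-negative")
  tot <- n_mouse_aligned + n_human_aligned
  if (tot == 0) {
    warning("no aligned reads; contamination fraction undefined")
    return(NA_real_)
  }
  n_mouse_aligned / tot
}

#' Export a strategy result as SAM files plus an unaligned-id list
#'
#' @param result a `strategy_result`.
#' @param reads the aligned `read_set`.
#' @param index the `seed_index` used.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
export_strategy_result <- function(result, reads, index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (side in c("human", "mouse")) {
    aln <- result[[side]]
    if (nrow(aln) == 0) next
    p <- file.path(dir, sprintf("%s_%s.sam", result$strategy, side))
    emit_sam(aln, reads, index, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, sprintf("%s_unaligned.txt", result$strategy))
  writeLines(result$unaligned_ids, p)
  invisible(c(paths, p))
}
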