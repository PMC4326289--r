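#' Alignment scoring scheme
#'
#' Defaults: match +1, mismatch -2, gap open -4, gap extend -1 (a gap of
#' length L costs `gap_open + L * gap_extend`). Any consistent scheme works
#' for comparing the handling strategies; only relative scores matter.
#'
#' @param match,mismatch,gap_open,gap_extend integer scores.
#' @return list of class `aln_scoring`.
#' @export
aln_scoring <- function(match = 1L, mismatch = -2L, gap_open = -4L,
                        gap_extend = -1L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "aln_scoring")
}

#' Build a seed index over one or more genomes
#'
#' Chromosomes are registered under namespaced names `<genome>:<chrom>`, so
#' a single index can hold both the host and graft references — the basis of
#' the combined-reference strategy.
#'
#' @param genomes an `xeno_genome` or a list of them (unique names).
#' @param k k-mer size (>= 8, default 15).
#' @return an object of class `seed_index`.
#' @export
build_index <- function(genomes, k = 15L) {
  if (inherits(genomes, "xeno_genome")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 0, all(vapply(genomes, inherits, TRUE, "xeno_genome")))
  if (k < 8) stop("k must be >= 8")
  gnames <- vapply(genomes, function(g) g$name, "")
  if (anyDuplicated(gnames)) stop("duplicate genome names: ", gnames[duplicated(gnames)][1])
  seqs <- character(0)
  nms <- character(0)
  for (g in genomes) {
    seqs <- c(seqs, unname(g$seqs))
    nms <- c(nms, paste0(g$name, ":", names(g$seqs)))
  }
  ptr <- cpp_build_index(seqs, nms, as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), chrom_names = nms,
                 chrom_lengths = setNames(nchar(seqs), nms),
                 genome_names = gnames),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> k=%d over %d chromosome(s) from genome(s): %s\n",
              x$k, length(x$chrom_names), paste(x$genome_names, collapse = ", ")))
  invisible(x)
}

# Index contents as a (kmer, chrom, pos) table; small genomes only.
index_kmer_table <- function(index) {
  d <- cpp_index_kmers(index$ptr)
  data.frame(key = d$key, chrom = index$chrom_names[d$chrom], pos = d$pos,
             stringsAsFactors = FALSE)
}

#' Align reads against a seed index
#'
#' Seed-and-extend: non-overlapping k-mer seeds are looked up in the index,
#' candidate loci (both strands) are extended by a banded fitting alignment
#' (read global, affine gaps), and the best-scoring locus is reported. A
#' read whose top score is attained at more than one distinct locus is
#' returned with `mapped = FALSE`, `unique = FALSE` and `mapq = 0`
#' (unique-best-match semantics). Otherwise
#' `mapq = min(60, 2 * (best - second_best))`.
#'
#' @param reads a `read_set`, or a character vector of sequences.
#' @param index a [build_index()] result.
#' @param scoring an [aln_scoring()].
#' @param band half-width of the extension band around the seed diagonal.
#' @param max_hits_per_seed seeds occurring more often than this are skipped.
#' @return data frame of alignment records: `read_id`, `ref_chrom`
#'   (namespaced), `pos` (0-based leftmost), `strand`, `score`, `mapq`,
#'   `cigar`, `mapped`, `unique`, `n_best`, `qlen`.
#' @export
align_reads <- function(reads, index, scoring = aln_scoring(), band = 8L,
                        max_hits_per_seed = 256L) {
  stopifnot(inherits(index, "seed_index"))
  if (is.character(reads)) {
    ids <- if (!is.null(names(reads))) names(reads) else paste0("read", seq_along(reads))
    seqs <- unname(reads)
  } else {
    ids <- reads$read_id
    seqs <- reads$sequence
  }
  r <- cpp_align_reads(index$ptr, seqs, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend,
                       as.integer(band), as.integer(max_hits_per_seed))
  data.frame(read_id = ids,
             ref_chrom = ifelse(is.na(r$chrom), NA_character_,
                                index$chrom_names[r$chrom]),
             pos = r$pos, strand = r$strand, score = r$score, mapq = r$mapq,
             cigar = r$cigar, mapped = r$mapped, unique = r$unique,
             n_best = r$n_best, qlen = r$qlen, stringsAsFactors = FALSE)
}

#' Successfully-aligned criterion
#'
#' A read counts as successfully aligned when it is mapped to a unique best
#' locus with an alignment score of at least `floor(min_frac * read_length *
#' match)` — an end-to-end identity floor mimicking default aligner
#' sensitivity.
#'
#' @param aln alignment records from [align_reads()].
#' @param scoring the scoring scheme used.
#' @param min_frac score floor as a fraction of the perfect score.
#' @param min_score optional absolute score floor overriding `min_frac`.
#' @return logical vector.
#' @export
is_aligned_ok <- function(aln, scoring = aln_scoring(), min_frac = 0.6,
                          min_score = NULL) {
  floor_score <- if (!is.null(min_score)) min_score
                 else floor(min_frac * aln$qlen * scoring$match)
  aln$mapped & aln$unique & !is.na(aln$score) & aln$score >= floor_score
}

#' Exhaustive alignment oracle
#'
#' Scans every position of every chromosome on both strands with an
#' unrestricted affine-gap fitting alignment and reports the best score and
#' every locus attaining it. Quadratic in genome size; intended for small
#' references.
#'
#' @param read a single read sequence.
#' @param genomes an `xeno_genome` or list of them (namespaced like
#'   [build_index()]).
#' @param scoring an [aln_scoring()].
#' @return list with `score` and `loci` (data frame `chrom`, `strand`,
#'   `pos`).
#' @export
oracle_align <- function(read, genomes, scoring = aln_scoring()) {
  if (inherits(genomes, "xeno_genome")) genomes <- list(genomes)
  seqs <- character(0)
  nms <- character(0)
  for (g in genomes) {
    seqs <- c(seqs, unname(g$seqs))
    nms <- c(nms, paste0(g$name, ":", names(g$seqs)))
  }
  r <- cpp_oracle_align(seqs, read, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)
  list(score = r$score,
       loci = data.frame(chrom = nms[r$chrom], strand = r$strand,
                         pos = r$start, stringsAsFactors = FALSE))
}

# --- SAM emission / ingestion ----------------------------------------------

#' Emit alignment records as SAM
#'
#' Minimal SAM: an `@HD`/`@SQ` header and one primary record per read.
#' Sequences are written in aligned orientation (reverse-complemented for
#' minus-strand alignments, FLAG bit 16), positions are converted to
#' 1-based, and the alignment score is carried in the `AS:i` tag. Unmapped
#' reads (including unique-best ties) get FLAG 4.
#'
#' @param aln alignment records from [align_reads()].
#' @param reads the `read_set` that was aligned (for sequences/qualities).
#' @param index the `seed_index` used (for the `@SQ` header).
#' @param path optional output path; when `NULL` the SAM lines are returned.
#' @return `path` (invisibly) or a character vector of SAM lines.
#' @export
emit_sam <- function(aln, reads, index, path = NULL) {
  ord <- match(aln$read_id, reads$read_id)
  seqs <- reads$sequence[ord]
  quals <- vapply(seq_along(seqs), function(i) {
    strrep(intToUtf8(reads$quality[ord[i]] + 33L), nchar(seqs[i]))
  }, "")
  minus <- !is.na(aln$strand) & aln$strand == "-" & aln$mapped
  seqs[minus] <- revcomp(seqs[minus])
  quals[minus] <- vapply(quals[minus], function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""), "",
                         USE.NAMES = FALSE)
  flag <- ifelse(aln$mapped, ifelse(minus, 16L, 0L), 4L)
  rec <- paste(aln$read_id, flag,
               ifelse(aln$mapped, aln$ref_chrom, "*"),
               ifelse(aln$mapped, aln$pos + 1L, 0L),
               ifelse(aln$mapped, aln$mapq, 0L),
               ifelse(aln$mapped, aln$cigar, "*"),
               "*", 0L, 0L, seqs, quals,
               ifelse(is.na(aln$score), "AS:i:0", paste0("AS:i:", aln$score)),
               sep = "\t")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", index$chrom_names,
                   unname(index$chrom_lengths)))
  out <- c(hdr, rec)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(path)
}

#' Ingest SAM alignments
#'
#' Parses primary records of a SAM file (or character vector of lines) back
#' into alignment records; positions become 0-based, FLAG bit 16 sets the
#' strand and bit 4 the unmapped state. Secondary/supplementary records
#' (bits 256/2048) are dropped. Reference names must be resolvable in the
#' supplied index when one is given.
#'
#' @param sam path to a SAM file, or a character vector of SAM lines.
#' @param index optional `seed_index` used to validate reference names.
#' @return alignment records as from [align_reads()] (with `n_best = NA`).
#' @export
ingest_sam <- function(sam, index = NULL) {
  lines <- if (length(sam) == 1 && file.exists(sam)) readLines(sam) else sam
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0) {
    return(data.frame(read_id = character(), ref_chrom = character(),
                      pos = integer(), strand = character(), score = integer(),
                      mapq = integer(), cigar = character(), mapped = logical(),
                      unique = logical(), n_best = integer(), qlen = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 11))
    stop("malformed SAM record at line ", which(nfield < 11)[1] + (length(lines) - length(body)))
  f <- function(i) vapply(parts, `[`, "", i)
  flag_all <- suppressWarnings(as.integer(f(2)))
  if (anyNA(flag_all))
    stop("malformed SAM FLAG at line ",
         which(is.na(flag_all))[1] + (length(lines) - length(body)))
  keep <- bitwAnd(flag_all, 256L) == 0L & bitwAnd(flag_all, 2048L) == 0L
  parts <- parts[keep]
  flag <- flag_all[keep]
  f <- function(i) vapply(parts, `[`, "", i)
  mapped <- bitwAnd(flag, 4L) == 0L
  rname <- f(3)
  if (!is.null(index) && any(mapped & !(rname %in% index$chrom_names)))
    stop("SAM reference name not present in index: ",
         rname[mapped & !(rname %in% index$chrom_names)][1])
  score <- vapply(parts, function(p) {
    as_tag <- grep("^AS:i:", p[-(1:11)], value = TRUE)
    if (length(as_tag)) as.integer(sub("^AS:i:", "", as_tag[1])) else NA_integer_
  }, 1L)
  mapq <- as.integer(f(5))
  data.frame(read_id = f(1),
             ref_chrom = ifelse(mapped, rname, NA_character_),
             pos = ifelse(mapped, as.integer(f(4)) - 1L, NA_integer_),
             strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                             NA_character_),
             score = score, mapq = mapq,
             cigar = ifelse(mapped, f(6), NA_character_),
             mapped = mapped, unique = mapped & mapq > 0L,
             n_best = NA_integer_,
             qlen = nchar(f(10)), stringsAsFactors = FALSE)
}
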