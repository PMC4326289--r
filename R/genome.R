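#' Genome container
#'
#' A genome is a named set of chromosome sequences over the `ACGT` alphabet.
#' Chromosome and genome names may not contain `_` or `:` — those characters
#' delimit the read-identifier truth encoding and the namespaced chromosome
#' names used by the combined-reference index.
#'
#' @param name genome identifier (e.g. `"human"`).
#' @param seqs named character vector of chromosome sequences.
#' @return an object of class `xeno_genome`.
#' @export
genome <- function(name, seqs) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  seqs <- setNames(as.character(seqs), names(seqs))
  if (length(seqs) > 0 && (is.null(names(seqs)) || anyDuplicated(names(seqs)) ||
                           any(!nzchar(names(seqs)))))
    stop("chromosome names must be unique and non-empty")
  if (grepl("[_:]", name) || any(grepl("[_:]", names(seqs))))
    stop("genome and chromosome names may not contain '_' or ':'")
  if (length(seqs) > 0 && any(grepl("[^ACGT]", seqs)))
    stop("sequences must be over the ACGT alphabet")
  structure(list(name = name, seqs = seqs), class = "xeno_genome")
}

#' @export
print.xeno_genome <- function(x, ...) {
  cat(sprintf("<xeno_genome> %s: %d chromosome(s), %s bases total\n",
              x$name, length(x$seqs),
              format(sum(nchar(x$seqs)), big.mark = ",")))
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param g an `xeno_genome`.
#' @return named integer vector of chromosome lengths.
#' @export
genome_lengths <- function(g) {
  stopifnot(inherits(g, "xeno_genome"))
  setNames(nchar(g$seqs), names(g$seqs))
}

#' Write / read a genome as FASTA
#'
#' Thin wrappers over Biostrings; `read_genome_fasta()` uppercases sequences
#' and keeps only the first whitespace-delimited token of each header.
#'
#' @param g an `xeno_genome`.
#' @param path FASTA file path.
#' @param name genome identifier to attach on read.
#' @return `write_genome_fasta()` returns `path` invisibly;
#'   `read_genome_fasta()` returns an `xeno_genome`.
#' @export
write_genome_fasta <- function(g, path) {
  stopifnot(inherits(g, "xeno_genome"))
  ss <- Biostrings::DNAStringSet(g$seqs)
  names(ss) <- names(g$seqs)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path, name) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, "", 1L)
  genome(name, seqs)
}

# --- interval helpers (0-based, half-open) ---------------------------------

# Sort and merge overlapping/adjacent intervals within each chromosome.
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  out <- lapply(split(iv, iv$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

interval_total_length <- function(iv) {
  if (nrow(iv) == 0) return(0L)
  as.integer(sum(iv$end - iv$start))
}

#' Write / read intervals as 3-column BED
#'
#' BED uses the same 0-based half-open convention as the package internals,
#' so coordinates pass through unchanged.
#'
#' @param iv data frame with columns `chrom`, `start`, `end`.
#' @param path BED file path.
#' @return `write_bed()` returns `path` invisibly; `read_bed()` the interval
#'   data frame.
#' @export
write_bed <- function(iv, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(iv)))
  write.table(iv[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start", "end"),
                  colClasses = c("character", "integer", "integer"))
  d
}
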