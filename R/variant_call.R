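#' Phred score / error probability conversions
#'
#' A Phred score q corresponds to an error probability of `10^(-q/10)`;
#' score 13 is an error probability of 0.05012, the default variant-quality
#' cutoff used throughout.
#'
#' @param q Phred score (>= 0).
#' @param p error probability in (0, 1].
#' @return the converted value.
#' @export
phred_to_error_prob <- function(q) {
  stopifnot(all(q >= 0))
  10^(-q / 10)
}

#' @rdname phred_to_error_prob
#' @export
prob_to_phred <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  -10 * log10(p)
}

#' Pile up aligned reads on a reference
#'
#' Builds per-position base counts (and mean base qualities per observed
#' base) over the reference from mapped, uniquely-placed alignments.
#' Insertions contribute no reference base; deleted positions contribute no
#' observation. Alignment chromosome names may be namespaced
#' (`<genome>:<chrom>`); records on other genomes are ignored.
#'
#' @param aln alignment records ([align_reads()]), already restricted to the
#'   reads that should be piled up (mapped and unique).
#' @param reads the `read_set` holding the sequences/qualities.
#' @param reference the `xeno_genome` the alignments refer to.
#' @return a `pileup_table`: data frame with `chrom`, `pos` (0-based),
#'   `ref`, counts `cA`..`cT` and mean Phred qualities `qA`..`qT`, one row
#'   per covered position.
#' @export
pileup <- function(aln, reads, reference) {
  stopifnot(inherits(reference, "xeno_genome"))
  aln <- aln[aln$mapped & aln$unique, , drop = FALSE]
  plain <- sub(paste0("^", reference$name, ":"), "", aln$ref_chrom)
  keep <- plain %in% names(reference$seqs)
  aln <- aln[keep, , drop = FALSE]
  plain <- plain[keep]
  ord <- match(aln$read_id, reads$read_id)
  if (anyNA(ord)) stop("alignment read_id missing from read set")
  seqs <- reads$sequence[ord]
  minus <- aln$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  chrom_idx <- match(plain, names(reference$seqs))
  cols <- cpp_pileup(unname(reference$seqs), chrom_idx, aln$pos, aln$cigar,
                     seqs, as.numeric(reads$quality[ord]))
  out <- data.frame(chrom = names(reference$seqs)[cols$chrom], pos = cols$pos,
                    ref = cols$ref, cA = cols$cA, cC = cols$cC, cG = cols$cG,
                    cT = cols$cT, qA = cols$qA, qC = cols$qC, qG = cols$qG,
                    qT = cols$qT, stringsAsFactors = FALSE)
  class(out) <- c("pileup_table", class(out))
  out
}

#' Call diploid SNVs from a pileup
#'
#' Independent-observation binomial genotype model with a uniform prior over
#' the genotypes ref/ref, ref/alt and alt/alt, where alt is the most
#' frequent non-reference base in the column. Per-base error probabilities
#' come from the observed base qualities. The call quality is
#' `-10*log10 P(ref/ref | data)`; a call is emitted when the maximum a
#' posteriori genotype is not ref/ref and depth is at least `min_depth`.
#'
#' @param columns a `pileup_table` from [pileup()].
#' @param min_depth minimum column depth to consider (default 3).
#' @return data frame of calls: `chrom`, `pos` (0-based), `ref_allele`,
#'   `alt_allele`, `genotype` (`het`/`hom_alt`), `qual`, `depth`.
#' @export
call_snvs <- function(columns, min_depth = 3L) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref_allele = character(), alt_allele = character(),
                      genotype = character(), qual = numeric(),
                      depth = integer(), stringsAsFactors = FALSE)
  if (nrow(columns) == 0) return(empty)
  cnt <- as.matrix(columns[, c("cA", "cC", "cG", "cT")])
  qm <- as.matrix(columns[, c("qA", "qC", "qG", "qT")])
  depth <- rowSums(cnt)
  ridx <- match(columns$ref, DNA_BASES)
  keep <- depth >= min_depth & !is.na(ridx)
  if (!any(keep)) return(empty)
  cnt <- cnt[keep, , drop = FALSE]
  qm <- qm[keep, , drop = FALSE]
  depth <- depth[keep]
  ridx <- ridx[keep]
  cols <- columns[keep, , drop = FALSE]
  n <- nrow(cnt)
  ii <- seq_len(n)
  # most frequent non-reference base (ties broken by base order A<C<G<T)
  cnt_nr <- cnt
  cnt_nr[cbind(ii, ridx)] <- -1L
  aidx <- max.col(cnt_nr, ties.method = "first")
  has_alt <- cnt[cbind(ii, aidx)] > 0
  if (!any(has_alt)) return(empty)
  sel <- which(has_alt)
  cnt <- cnt[sel, , drop = FALSE]
  qm <- qm[sel, , drop = FALSE]
  depth <- depth[sel]
  ridx <- ridx[sel]
  aidx <- aidx[sel]
  cols <- cols[sel, , drop = FALSE]
  ii <- seq_len(nrow(cnt))
  e <- phred_to_error_prob(qm)  # per-base-class error probability
  p_rr <- e / 3
  p_rr[cbind(ii, ridx)] <- 1 - e[cbind(ii, ridx)]
  p_aa <- e / 3
  p_aa[cbind(ii, aidx)] <- 1 - e[cbind(ii, aidx)]
  p_ra <- e / 3
  p_ra[cbind(ii, ridx)] <- (1 - e[cbind(ii, ridx)]) / 2 + e[cbind(ii, ridx)] / 6
  p_ra[cbind(ii, aidx)] <- (1 - e[cbind(ii, aidx)]) / 2 + e[cbind(ii, aidx)] / 6
  # zero-count classes contribute nothing; guard log(0) there
  safe_log <- function(m) { m[cnt == 0] <- 1; log(m) }
  l_rr <- rowSums(cnt * safe_log(p_rr))
  l_ra <- rowSums(cnt * safe_log(p_ra))
  l_aa <- rowSums(cnt * safe_log(p_aa))
  lmax <- pmax(l_rr, l_ra, l_aa)
  denom <- lmax + log(exp(l_rr - lmax) + exp(l_ra - lmax) + exp(l_aa - lmax))
  qual <- -10 / log(10) * (l_rr - denom)
  geno <- ifelse(l_aa >= l_ra & l_aa > l_rr, "hom_alt",
                 ifelse(l_ra > l_rr, "het", "ref"))
  emit <- geno != "ref"
  out <- data.frame(chrom = cols$chrom[emit], pos = cols$pos[emit],
                    ref_allele = DNA_BASES[ridx[emit]],
                    alt_allele = DNA_BASES[aidx[emit]],
                    genotype = geno[emit], qual = qual[emit],
                    depth = as.integer(depth[emit]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter variant calls on Phred quality
#'
#' Retains calls whose quality is at least `min_qual` (inclusive); the
#' default 13 corresponds to an error probability of about 5%.
#'
#' @param calls data frame from [call_snvs()].
#' @param min_qual minimum Phred-scaled call quality.
#' @return the retained calls.
#' @export
filter_calls <- function(calls, min_qual = 13) {
  stopifnot(min_qual >= 0)
  calls[calls$qual >= min_qual, , drop = FALSE]
}

#' Write / read variant calls as VCF v4.2
#'
#' Positions are converted to 1-based; the QUAL field carries the
#' Phred-scaled call quality and the genotype is written as `GT` in a single
#' sample column.
#'
#' @param calls data frame from [call_snvs()].
#' @param path VCF path.
#' @param sample sample name for the genotype column.
#' @return `write_vcf()` returns `path` invisibly; `read_vcf()` a calls data
#'   frame.
#' @export
write_vcf <- function(calls, path, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  gt <- ifelse(calls$genotype == "hom_alt", "1/1", "0/1")
  rec <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\t.\tGT\t%s",
                 calls$chrom, calls$pos + 1L, calls$ref_allele,
                 calls$alt_allele, calls$qual, gt)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref_allele = character(), alt_allele = character(),
                      genotype = character(), qual = numeric(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(body, "\t", fixed = TRUE)
  f <- function(i) vapply(parts, `[`, "", i)
  gt <- vapply(parts, function(p) if (length(p) >= 10) p[10] else "0/1", "")
  data.frame(chrom = f(1), pos = as.integer(f(2)) - 1L, ref_allele = f(4),
             alt_allele = f(5),
             genotype = ifelse(gt == "1/1", "hom_alt", "het"),
             qual = as.numeric(f(6)), stringsAsFactors = FALSE)
}
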