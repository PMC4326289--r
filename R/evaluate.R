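#' Confusion counts
#'
#' @param tp,fp,fn non-negative counts.
#' @param level one of `"alignment"`, `"variant"`, `"nonsynonymous"`.
#' @return list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, level = "alignment") {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, level = level),
            class = "confusion_counts")
}

#' False discovery and false negative rates
#'
#' `fdr = FP / (FP + TP)` among reported items; `fnr = FN / (FN + TP)` among
#' truth items. A zero denominator gives 0 with attribute `defined = FALSE`
#' (no discoveries means no false discoveries; no truth means nothing
#' missed).
#'
#' @param counts a [confusion_counts()].
#' @return a rate in `[0, 1]`.
#' @export
fdr <- function(counts) {
  d <- counts$fp + counts$tp
  if (d == 0) return(structure(0, defined = FALSE))
  counts$fp / d
}

#' @rdname fdr
#' @export
fnr <- function(counts) {
  d <- counts$fn + counts$tp
  if (d == 0) return(structure(0, defined = FALSE))
  counts$fn / d
}

#' Score a strategy's alignments against read truth
#'
#' A host-origin read is a true positive when it is aligned to the host
#' reference on the truth chromosome and strand within `pos_tolerance`
#' bases of its truth start. False positives are reads of any origin
#' aligned to the host reference elsewhere — a host read aligned to the
#' wrong host position counts both as a false positive (it is incorrectly
#' aligned) and as a false negative (it is not correctly aligned) — plus
#' graft reads aligned to the host reference. False negatives are
#' host-origin reads without a correct host alignment.
#'
#' @param result a `strategy_result`.
#' @param pos_tolerance positional slack in bases (indels shift leftmost
#'   coordinates; default 5).
#' @param host_name name of the host genome (truth `origin` label and
#'   namespace prefix of host chromosomes).
#' @return a `confusion_counts` at level `"alignment"`.
#' @export
score_alignments <- function(result, pos_tolerance = 5L, host_name = "human") {
  h <- result$human
  truth_h <- if (nrow(h)) parse_read_id(h$read_id) else NULL
  n_host_total <- 0L
  for (ids in list(h$read_id, result$mouse$read_id, result$unaligned_ids)) {
    if (length(ids))
      n_host_total <- n_host_total + sum(parse_read_id(ids)$origin == host_name)
  }
  if (nrow(h) == 0) return(confusion_counts(0L, 0L, n_host_total, "alignment"))
  aligned_chrom <- sub(paste0("^", host_name, ":"), "", h$ref_chrom)
  correct <- truth_h$origin == host_name &
    aligned_chrom == truth_h$chrom &
    h$strand == truth_h$strand &
    abs(h$pos - truth_h$start) <= pos_tolerance
  tp <- sum(correct)
  fp <- sum(!correct)          # misplaced host reads + graft leaks
  fn <- n_host_total - tp      # misplaced + unaligned host reads
  confusion_counts(tp, fp, fn, "alignment")
}

#' Score variant calls against planted truth
#'
#' Calls and truth SNVs match on (chrom, pos, alt allele); matching on the
#' allele and not position alone avoids inflating true positives. Truth
#' indels are excluded (SNV-level scoring).
#'
#' @param calls data frame from [call_snvs()]/[filter_calls()].
#' @param truth truth data frame from [mutate_genome()].
#' @return a `confusion_counts` at level `"variant"`.
#' @export
score_variants <- function(calls, truth) {
  tsnv <- truth[truth$vtype == "SNV", , drop = FALSE]
  tkey <- paste(tsnv$chrom, tsnv$pos, tsnv$alt_allele)
  ckey <- paste(calls$chrom, calls$pos, calls$alt_allele)
  tp <- sum(tkey %in% ckey)
  confusion_counts(tp = tp, fp = sum(!(ckey %in% tkey)),
                   fn = nrow(tsnv) - tp, level = "variant")
}

#' Classify the coding effect of SNVs
#'
#' Locates the containing CDS interval, rebuilds the affected codon with
#' strand-aware complementation (the reading frame is anchored at the CDS
#' start and runs across exons), and translates reference and mutated codon
#' with the standard genetic code.
#'
#' @param chrom,pos,alt vectors describing SNVs (0-based positions,
#'   reference-strand alt alleles).
#' @param genes per-interval gene data frame from [annotate_genes()].
#' @param reference the `xeno_genome` the coordinates refer to.
#' @return character vector: `"non_synonymous"`, `"synonymous"` or
#'   `"non_coding"`.
#' @export
classify_variant_effect <- function(chrom, pos, alt, genes, reference) {
  stopifnot(inherits(reference, "xeno_genome"))
  n <- length(pos)
  out <- rep("non_coding", n)
  if (n == 0 || nrow(genes) == 0) return(out)
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # per-gene CDS sequences and interval bookkeeping, built once
  gene_ids <- unique(genes$gene_id)
  gene_info <- lapply(gene_ids, function(gid) {
    d <- genes[genes$gene_id == gid, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    seqs <- substring(reference$seqs[[d$chrom[1]]], d$start + 1L, d$end)
    cds <- paste(seqs, collapse = "")  # genomic (+-strand) order
    if (nchar(cds) %% 3 != 0) stop("malformed gene model: ", gid)
    list(d = d, cds = cds, strand = d$strand[1],
         cum = cumsum(c(0L, d$end - d$start)))
  })
  names(gene_info) <- gene_ids
  for (i in seq_len(n)) {
    hit <- genes$chrom == chrom[i] & genes$start <= pos[i] & pos[i] < genes$end
    if (!any(hit)) next
    gid <- genes$gene_id[which(hit)[1]]
    gi <- gene_info[[gid]]
    row <- which(gi$d$start <= pos[i] & pos[i] < gi$d$end)[1]
    off_plus <- gi$cum[row] + (pos[i] - gi$d$start[row])  # 0-based, + orientation
    L <- nchar(gi$cds)
    if (gi$strand == "+") {
      cds_pos <- off_plus
      base_new <- alt[i]
      cds_seq <- gi$cds
    } else {
      cds_pos <- L - 1L - off_plus
      base_new <- comp[[alt[i]]]
      cds_seq <- revcomp(gi$cds)
    }
    ci <- cds_pos %/% 3L
    codon <- substr(cds_seq, ci * 3L + 1L, ci * 3L + 3L)
    codon_new <- codon
    substr(codon_new, cds_pos %% 3L + 1L, cds_pos %% 3L + 1L) <- base_new
    out[i] <- if (code[[codon]] == code[[codon_new]]) "synonymous" else "non_synonymous"
  }
  out
}

#' Score non-synonymous SNV detection
#'
#' Restricts variant-level scoring to non-synonymous SNVs: true positives
#' are called truth SNVs that are non-synonymous, false positives are
#' non-truth calls classified non-synonymous, false negatives are missed
#' non-synonymous truth SNVs.
#'
#' @inheritParams score_variants
#' @inheritParams classify_variant_effect
#' @return a `confusion_counts` at level `"nonsynonymous"`.
#' @export
score_nonsynonymous <- function(calls, truth, genes, reference) {
  tsnv <- truth[truth$vtype == "SNV", , drop = FALSE]
  t_ns <- if (nrow(tsnv)) classify_variant_effect(tsnv$chrom, tsnv$pos,
                                                  tsnv$alt_allele, genes,
                                                  reference) == "non_synonymous"
          else logical(0)
  tkey <- paste(tsnv$chrom, tsnv$pos, tsnv$alt_allele)
  ckey <- paste(calls$chrom, calls$pos, calls$alt_allele)
  called <- tkey %in% ckey
  fp_calls <- calls[!(ckey %in% tkey), , drop = FALSE]
  c_ns <- if (nrow(fp_calls)) classify_variant_effect(fp_calls$chrom, fp_calls$pos,
                                                      fp_calls$alt_allele, genes,
                                                      reference) == "non_synonymous"
          else logical(0)
  confusion_counts(tp = sum(called & t_ns), fp = sum(c_ns),
                   fn = sum(!called & t_ns), level = "nonsynonymous")
}

#' Assemble an accuracy report
#'
#' One row per (strategy, level) with counts and FDR/FNR.
#'
#' @param scored named list (by strategy) of lists of `confusion_counts`.
#' @return data frame with `strategy`, `level`, `tp`, `fp`, `fn`, `fdr`,
#'   `fnr`.
#' @export
accuracy_report <- function(scored) {
  rows <- list()
  for (strat in names(scored)) {
    for (cc in scored[[strat]]) {
      rows[[length(rows) + 1]] <- data.frame(
        strategy = strat, level = cc$level, tp = cc$tp, fp = cc$fp, fn = cc$fn,
        fdr = as.numeric(fdr(cc)), fnr = as.numeric(fnr(cc)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
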