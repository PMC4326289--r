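test_that("FDR and FNR follow their standard definitions", {
  expect_equal(fdr(confusion_counts(9, 1, 0)), 0.1)
  expect_equal(fnr(confusion_counts(9, 0, 1)), 0.1)
  expect_equal(fdr(confusion_counts(5, 0, 3)), 0)
  expect_equal(fnr(confusion_counts(5, 2, 0)), 0)
  z <- fdr(confusion_counts(0, 0, 4))
  expect_equal(as.numeric(z), 0)
  expect_false(attr(z, "defined"))
})

# A hand-built strategy result: 10 host reads (7 correctly aligned, 1
# misplaced, 2 unaligned) plus 1 graft read leaked into the host alignments.
# The misplaced host read counts as both a false positive and a false
# negative, giving (TP, FP, FN) = (7, 2, 3).
test_that("alignment scoring matches the hand-tallied fixture", {
  mk_aln <- function(id, chrom, pos, strand) {
    data.frame(read_id = id, ref_chrom = paste0("human:", chrom), pos = pos,
               strand = strand, score = 100L, mapq = 60L, cigar = "100M",
               mapped = TRUE, unique = TRUE, n_best = 1L, qlen = 100L,
               stringsAsFactors = FALSE)
  }
  correct <- do.call(rbind, lapply(1:7, function(i)
    mk_aln(sprintf("human_chr1_%d_+_0_%d", i * 500, i), "chr1", i * 500, "+")))
  misplaced <- mk_aln("human_chr1_4000_+_0_8", "chr1", 9000, "+")
  leak <- mk_aln("mouse_chr1_100_+_0_9", "chr1", 3100, "+")
  res <- xenosim:::new_strategy_result(
    "direct", human = rbind(correct, misplaced, leak),
    mouse = correct[0, ],
    unaligned_ids = c("human_chr1_7000_+_0_10", "human_chr2_40_-_0_11"),
    n_reads = 11L)
  cc <- score_alignments(res, pos_tolerance = 5, host_name = "human")
  expect_equal(cc$tp, 7)
  expect_equal(cc$fp, 2)
  expect_equal(cc$fn, 3)
  # positional tolerance: within 5 bp still counts as correct
  shifted <- mk_aln("human_chr1_600_+_0_12", "chr1", 604, "+")
  res2 <- xenosim:::new_strategy_result("direct", human = shifted,
                                        mouse = correct[0, ],
                                        unaligned_ids = character(0),
                                        n_reads = 1L)
  expect_equal(score_alignments(res2)$tp, 1)
  # strand mismatches do not count as correct
  flipped <- mk_aln("human_chr1_600_-_0_13", "chr1", 600, "+")
  res3 <- xenosim:::new_strategy_result("direct", human = flipped,
                                        mouse = correct[0, ],
                                        unaligned_ids = character(0),
                                        n_reads = 1L)
  expect_equal(score_alignments(res3)$tp, 0)
  expect_equal(score_alignments(res3)$fp, 1)
})

test_that("variant scoring matches on position and allele", {
  truth <- data.frame(chrom = "chr1", pos = c(5L, 9L), ref_allele = c("A", "C"),
                      alt_allele = c("T", "G"), vtype = "SNV",
                      stringsAsFactors = FALSE)
  calls <- data.frame(chrom = "chr1", pos = c(5L, 7L), ref_allele = c("A", "G"),
                      alt_allele = c("T", "A"), genotype = "het", qual = 40,
                      stringsAsFactors = FALSE)
  cc <- score_variants(calls, truth)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(1, 1, 1))
  # identical call set: perfect score
  calls2 <- data.frame(chrom = "chr1", pos = c(5L, 9L), ref_allele = c("A", "C"),
                       alt_allele = c("T", "G"), genotype = "het", qual = 40,
                       stringsAsFactors = FALSE)
  cc2 <- score_variants(calls2, truth)
  expect_equal(c(cc2$fp, cc2$fn), c(0, 0))
  # no calls: everything missed
  cc3 <- score_variants(calls2[0, ], truth)
  expect_equal(cc3$fn, 2)
  # a call at the right position but wrong allele is not a true positive
  calls4 <- data.frame(chrom = "chr1", pos = 5L, ref_allele = "A",
                       alt_allele = "G", genotype = "het", qual = 40,
                       stringsAsFactors = FALSE)
  cc4 <- score_variants(calls4, truth)
  expect_equal(c(cc4$tp, cc4$fp, cc4$fn), c(0, 1, 2))
  # truth indels are excluded from SNV-level scoring
  truth5 <- rbind(truth, data.frame(chrom = "chr1", pos = 20L, ref_allele = "AC",
                                    alt_allele = "", vtype = "DEL",
                                    stringsAsFactors = FALSE))
  expect_equal(score_variants(calls2, truth5)$fn, 0)
})

test_that("codon-level effect classification follows the standard genetic code", {
  # chr1: 12 bases of CDS (+ strand gene), GGA at codon 2 (positions 3-5)
  seq <- paste0("ATG", "GGA", "CCT", "TAA", "ACGTACGTAC")
  ref <- genome("human", c(chr1 = seq))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 0L, end = 12L, exon_rank = 1L,
                      stringsAsFactors = FALSE)
  # GGA -> GGG: Gly -> Gly (synonymous, third codon position 5)
  expect_identical(classify_variant_effect("chr1", 5L, "G", genes, ref),
                   "synonymous")
  # GGA -> GAA: Gly -> Glu (non-synonymous, second codon position 4)
  expect_identical(classify_variant_effect("chr1", 4L, "A", genes, ref),
                   "non_synonymous")
  # outside any CDS interval
  expect_identical(classify_variant_effect("chr1", 15L, "A", genes, ref),
                   "non_coding")
})

test_that("effect classification is strand-aware across exon boundaries", {
  # minus-strand gene over two exons; CDS (read 5'->3' on -) must translate
  # consistently. Genomic [2,8) + [10,14): 10 bases total? Use 12: [2,8)+[10,16).
  gseq <- paste0("GG", "TTACGT", "XX", "ACGTAA", "GG")
  gseq <- gsub("X", "C", gseq)
  ref <- genome("human", c(chr1 = gseq))
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "-",
                      start = c(2L, 10L), end = c(8L, 16L), exon_rank = c(2L, 1L),
                      stringsAsFactors = FALSE)
  # CDS on minus strand = revcomp("TTACGT" + "ACGTAA") = "TTACGT|ACGTAA" ->
  # revcomp gives "TTACGTACGTAA" reversed-complemented: check both mutation
  # classes relative to a brute-force translation
  translate1 <- function(s) {
    sapply(seq(1, nchar(s) - 2, by = 3), function(i)
      Biostrings::GENETIC_CODE[[substr(s, i, i + 2)]])
  }
  cds_minus <- as.character(revcomp(paste0(substr(gseq, 3, 8), substr(gseq, 11, 16))))
  for (gpos in c(3L, 5L, 11L, 14L)) {
    for (alt in setdiff(c("A", "C", "G", "T"), substr(gseq, gpos + 1, gpos + 1))) {
      got <- classify_variant_effect("chr1", gpos, alt, genes, ref)
      # brute force: rebuild the mutated genome, re-extract the CDS, translate
      mut <- gseq
      substr(mut, gpos + 1, gpos + 1) <- alt
      cds_mut <- as.character(revcomp(paste0(substr(mut, 3, 8), substr(mut, 11, 16))))
      want <- if (identical(translate1(cds_minus), translate1(cds_mut)))
        "synonymous" else "non_synonymous"
      expect_identical(got, want)
    }
  }
})

test_that("non-synonymous counts are dominated by variant-level counts", {
  pair <- make_pair(40000, 8, seed = 401)
  mut <- mutate_genome(pair$host, 0.01, seed = 402)
  rs <- simulate_reads(mut$genome, "whole", 100, 1e-4, depth = 30, seed = 403,
                       coord_map = mut$maps)
  idx <- build_index(pair$host)
  res <- run_direct(rs, idx)
  cols <- pileup(res$human, rs, pair$host)
  calls <- filter_calls(call_snvs(cols), 13)
  v <- score_variants(calls, mut$truth)
  ns <- score_nonsynonymous(calls, mut$truth, pair$ann$genes, pair$host)
  expect_lte(ns$tp, v$tp)
  expect_lte(ns$fp, v$fp)
  expect_lte(ns$fn, v$fn)
  expect_gt(v$tp, 0)
})

test_that("accuracy reports collect counts and rates per strategy and level", {
  scored <- list(direct = list(confusion_counts(9, 1, 3, "alignment"),
                               confusion_counts(4, 2, 1, "variant")))
  rep <- accuracy_report(scored)
  expect_identical(nrow(rep), 2L)
  expect_equal(rep$fdr[rep$level == "alignment"], 0.1)
  expect_equal(rep$fnr[rep$level == "alignment"], 0.25)
})
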