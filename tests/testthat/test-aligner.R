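test_that("index construction validates input and registers namespaced chromosomes", {
  g <- generate_ancestor(2000, 2, 0.5, seed = 1)
  idx <- build_index(g, k = 11)
  expect_setequal(idx$chrom_names, c("human:chr1", "human:chr2"))
  expect_error(build_index(g, k = 5), "k must be")
  expect_error(build_index(list(g, g)), "duplicate genome")
  # empty genome set gives an empty index
  idx0 <- build_index(list(), k = 11)
  expect_length(idx0$chrom_names, 0)
})

test_that("every indexed position reproduces its k-mer, and a union index equals merged per-genome indexes", {
  a <- generate_ancestor(600, 1, 0.5, seed = 2, name = "human")
  b <- generate_ancestor(500, 1, 0.5, seed = 3, name = "mouse")
  k <- 11
  idx <- build_index(list(a, b), k = k)
  tab <- xenosim:::index_kmer_table(idx)
  seqs <- c("human:chr1" = a$seqs[[1]], "mouse:chr1" = b$seqs[[1]])
  # slice each stored position and re-encode; must equal the stored key
  enc <- function(s) {
    v <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T")) - 1
    sum(v * 4^(rev(seq_along(v)) - 1))
  }
  sl <- substring(seqs[tab$chrom], tab$pos + 1, tab$pos + k)
  expect_true(all(vapply(sl, enc, 1) == tab$key))
  # union property
  t_a <- xenosim:::index_kmer_table(build_index(a, k = k))
  t_b <- xenosim:::index_kmer_table(build_index(b, k = k))
  key <- function(d) sort(paste(d$key, d$chrom, d$pos))
  expect_identical(key(tab), sort(c(key(t_a), key(t_b))))
})

test_that("exact unique substrings map to their source locus with a full-match cigar", {
  g <- generate_ancestor(4000, 1, 0.5, seed = 11)
  read <- substr(g$seqs[[1]], 501, 600)
  idx <- build_index(g)
  a <- align_reads(c(r = read), idx)
  expect_true(a$mapped && a$unique)
  expect_equal(a$pos, 500)
  expect_identical(a$cigar, "100M")
  expect_equal(a$score, 100)
  expect_identical(a$strand, "+")
  # a read shorter than the seed size is unmapped
  short <- align_reads(c(s = substr(read, 1, 10)), idx)
  expect_false(short$mapped)
})

test_that("a planted duplication triggers the unique-best tie rule", {
  seg <- generate_ancestor(120, 1, 0.5, seed = 21)$seqs[[1]]
  filler <- generate_ancestor(600, 1, 0.5, seed = 22)$seqs[[1]]
  dup <- genome("human", c(chr1 = paste0(seg, filler, seg)))
  idx <- build_index(dup)
  a <- align_reads(c(r = substr(seg, 11, 90)), idx)
  expect_false(a$mapped)
  expect_false(a$unique)
  expect_equal(a$mapq, 0)
  expect_equal(a$n_best, 2)
})

test_that("aligning a reverse complement flips the strand but keeps the locus", {
  g <- generate_ancestor(3000, 1, 0.5, seed = 31)
  idx <- build_index(g)
  read <- substr(g$seqs[[1]], 1001, 1080)
  fw <- align_reads(c(f = read), idx)
  rc <- align_reads(c(r = revcomp(read)), idx)
  expect_equal(rc$pos, fw$pos)
  expect_equal(rc$score, fw$score)
  expect_setequal(c(fw$strand, rc$strand), c("+", "-"))
})

test_that("seeded alignment equals the exhaustive oracle on random small instances", {
  set.seed(42)
  for (case in 1:40) {
    g <- generate_ancestor(sample(300:900, 1), sample(1:2, 1), runif(1, 0.35, 0.6),
                           seed = 1000 + case)
    idx <- build_index(g, k = 11)
    ch <- sample(names(g$seqs), 1)
    len <- sample(c(50, 100), 1)
    if (nchar(g$seqs[[ch]]) <= len) next
    st <- sample(nchar(g$seqs[[ch]]) - len, 1)
    rd <- substr(g$seqs[[ch]], st, st + len - 1)
    for (e in seq_len(sample(0:3, 1))) {
      p <- sample(len, 1)
      substr(rd, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(rd, p, p)), 1)
    }
    if (runif(1) < 0.5) rd <- revcomp(rd)
    a <- align_reads(rd, idx, band = 8)
    o <- oracle_align(rd, g)
    expect_equal(a$score, o$score)
    expect_equal(a$n_best > 1, nrow(o$loci) > 1)
    if (nrow(o$loci) == 1) {
      expect_equal(a$pos, o$loci$pos)
      expect_identical(a$strand, o$loci$strand)
      expect_identical(a$ref_chrom, o$loci$chrom)
    }
  }
})

test_that("planting an extra mismatch never increases the alignment score", {
  set.seed(7)
  g <- generate_ancestor(5000, 1, 0.5, seed = 41)
  idx <- build_index(g)
  for (case in 1:25) {
    st <- sample(4900, 1)
    src <- substr(g$seqs[[1]], st, st + 99)
    rd <- src
    prev <- align_reads(rd, idx)$score
    # distinct positions, each flipped away from the source base
    for (p in sample(100, 4)) {
      substr(rd, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(src, p, p)), 1)
      cur <- align_reads(rd, idx)$score
      if (is.na(cur)) cur <- -Inf  # all seeds lost: treat as unaligned
      expect_lte(cur, if (is.na(prev)) Inf else prev)
      prev <- cur
    }
  }
})

test_that("SAM emission and ingestion are inverse operations", {
  g <- generate_ancestor(8000, 2, 0.5, seed = 51)
  rs <- simulate_reads(g, "whole", 60, 0.01, depth = 1, seed = 52)
  idx <- build_index(g)
  aln <- align_reads(rs, idx)
  sam <- emit_sam(aln, rs, idx)
  back <- ingest_sam(sam, idx)
  expect_identical(back$read_id, aln$read_id)
  expect_identical(back$mapped, aln$mapped)
  m <- aln$mapped
  expect_identical(back$ref_chrom[m], aln$ref_chrom[m])
  expect_identical(back$pos[m], aln$pos[m])
  expect_identical(back$strand[m], aln$strand[m])
  expect_identical(back$cigar[m], aln$cigar[m])
  expect_equal(back$score[m], aln$score[m])
  expect_equal(back$mapq, aln$mapq)
  # file round trip too
  f <- tempfile(fileext = ".sam")
  emit_sam(aln, rs, idx, f)
  expect_identical(ingest_sam(f, idx), back)
})

test_that("SAM ingestion converts 1-based positions and honors flags", {
  hdr <- c("@HD\tVN:1.6", "@SQ\tSN:human:chr1\tLN:500")
  rec <- paste("r1", 0, "human:chr1", 101, 60, "10M", "*", 0, 0,
               "ACGTACGTAC", "IIIIIIIIII", "AS:i:10", sep = "\t")
  unm <- paste("r2", 4, "*", 0, 0, "*", "*", 0, 0, "ACGTACGTAC",
               "IIIIIIIIII", sep = "\t")
  got <- ingest_sam(c(hdr, rec, unm))
  expect_equal(got$pos[1], 100)
  expect_true(got$mapped[1])
  expect_false(got$mapped[2])
  expect_true(all(!got$mapped[got$ref_chrom %in% NA]))
  expect_error(ingest_sam(c(hdr, "r3\t0\tchr1")), "malformed")
})
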