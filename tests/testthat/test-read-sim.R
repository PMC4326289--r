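test_that("profile names parse to their parameter triples", {
  p <- sim_profile("mH.len100.eL")
  expect_equal(p$mutation_rate, 0.01)
  expect_equal(p$read_length, 100L)
  expect_equal(p$error_rate, 0.0001)
  p2 <- sim_profile("mL.len050.eH")
  expect_equal(p2$mutation_rate, 0)
  expect_equal(p2$read_length, 50L)
  expect_equal(p2$error_rate, 0.01)
  expect_error(sim_profile("mX.len100.eL"), "grammar|match")
})

test_that("zero mutation rate leaves the genome untouched (ideal case)", {
  g <- generate_ancestor(20000, 2, 0.45, seed = 1)
  mut <- mutate_genome(g, 0, seed = 2)
  expect_identical(mut$genome$seqs, g$seqs)
  expect_identical(nrow(mut$truth), 0L)
})

test_that("mutation counts respect the rate and the 9:1 SNV:indel split", {
  g <- generate_ancestor(100000, 1, 0.5, seed = 11)
  mut <- mutate_genome(g, 0.01, snv_fraction = 0.9, seed = 12)
  n_snv <- sum(mut$truth$vtype == "SNV")
  n_indel <- sum(mut$truth$vtype != "SNV")
  expect_within_binom99(n_snv, 100000, 0.01 * 0.9)
  expect_within_binom99(n_indel, 100000, 0.01 * 0.1)
  # every SNV's reference allele matches the reference sequence
  snv <- mut$truth[mut$truth$vtype == "SNV", ]
  expect_identical(substring(g$seqs[[1]], snv$pos + 1, snv$pos + 1),
                   snv$ref_allele)
  expect_true(all(snv$alt_allele != snv$ref_allele))
})

test_that("replaying the truth list reproduces the mutated genome exactly", {
  g <- generate_ancestor(30000, 2, 0.45, seed = 21)
  mut <- mutate_genome(g, 0.02, seed = 22)
  for (ch in names(g$seqs)) {
    replayed <- replay_truth(g$seqs[[ch]],
                             mut$truth[mut$truth$chrom == ch, , drop = FALSE])
    expect_identical(replayed, mut$genome$seqs[[ch]])
  }
})

test_that("read count follows the depth formula and regions are honored", {
  g <- generate_ancestor(10000, 1, 0.5, seed = 31)
  rs <- simulate_reads(g, "whole", read_length = 100, error_rate = 0,
                       depth = 6, seed = 32)
  expect_equal(nrow(rs), round(6 * 10000 / 100))
  reg <- data.frame(chrom = "chr1", start = 2000L, end = 4000L)
  rs2 <- simulate_reads(g, reg, read_length = 50, error_rate = 0, depth = 10,
                        seed = 33)
  expect_equal(nrow(rs2), round(10 * 2000 / 50))
  expect_true(all(rs2$start >= 2000 & rs2$start < 4000))
  # short regions are skipped with a warning
  reg2 <- rbind(reg, data.frame(chrom = "chr1", start = 100L, end = 120L))
  expect_warning(simulate_reads(g, reg2, read_length = 50, error_rate = 0,
                                depth = 2, seed = 34), "skipped")
})

test_that("error-free reads equal their strand-aware source substrings", {
  g <- generate_ancestor(10000, 1, 0.5, seed = 41)
  rs <- simulate_reads(g, "whole", read_length = 80, error_rate = 0,
                       depth = 4, seed = 42)
  src <- unname(substring(g$seqs[rs$chrom], rs$start + 1, rs$start + 80))
  src[rs$strand == "-"] <- revcomp(src[rs$strand == "-"])
  expect_identical(rs$sequence, src)
  expect_true(all(rs$n_err == 0))
  expect_true(all(rs$quality == 40))
})

test_that("planted sequencing errors match the configured rate", {
  g <- generate_ancestor(20000, 1, 0.5, seed = 51)
  rs <- simulate_reads(g, "whole", read_length = 100, error_rate = 0.01,
                       depth = 10, seed = 52)
  total_bases <- sum(nchar(rs$sequence))
  expect_gte(total_bases, 1e5)
  expect_within_binom99(sum(rs$n_err), total_bases, 0.01)
  # flat quality encodes the error rate
  expect_true(all(rs$quality == 20))
  # n_err agrees with a direct comparison against the source substring
  src <- substring(g$seqs[rs$chrom], rs$start + 1, rs$start + 100)
  src[rs$strand == "-"] <- revcomp(src[rs$strand == "-"])
  mism <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                 rs$sequence[1:200], src[1:200])
  expect_equal(unname(mism), rs$n_err[1:200])
})

test_that("read ids round-trip their truth tuples", {
  g <- generate_ancestor(5000, 2, 0.5, seed = 61)
  rs <- simulate_reads(g, "whole", read_length = 50, error_rate = 0.01,
                       depth = 2, seed = 62)
  tr <- parse_read_id(rs$read_id)
  expect_identical(tr$origin, rs$origin)
  expect_identical(tr$chrom, rs$chrom)
  expect_identical(tr$start, rs$start)
  expect_identical(tr$strand, rs$strand)
  expect_identical(tr$n_err, rs$n_err)
  expect_error(parse_read_id("not-an-id"), "unparseable")
})

test_that("mixing splits counts exactly and conserves reads", {
  g <- generate_ancestor(20000, 1, 0.5, seed = 71, name = "human")
  m <- generate_ancestor(20000, 1, 0.5, seed = 72, name = "mouse")
  h <- simulate_reads(g, "whole", 50, 0, depth = 3, seed = 73)
  gr <- simulate_reads(m, "whole", 50, 0, depth = 3, seed = 74)
  mx <- mix_reads(h, gr, c(9, 1), 600, seed = 75)
  expect_equal(nrow(mx), 600)
  expect_equal(sum(mx$origin == "human"), 540)
  expect_equal(sum(mx$origin == "mouse"), 60)
  # conservation: the mixture is a subset-union of the two pools
  expect_true(all(mx$read_id[mx$origin == "human"] %in% h$read_id))
  expect_true(all(mx$read_id[mx$origin == "mouse"] %in% gr$read_id))
  expect_false(anyDuplicated(mx$read_id) > 0)
  # 1:0 takes everything from the host pool
  mx2 <- mix_reads(h, gr, c(1, 0), 100, seed = 76)
  expect_true(all(mx2$origin == "human"))
  # deficient pool errors with the pool name
  expect_error(mix_reads(h, gr, c(1, 9), 2000, seed = 77), "graft")
})

test_that("effective depth is the depth-fraction product", {
  expect_equal(effective_depth(60, 0.9), 54)
  expect_equal(effective_depth(60, 0.5), 30)
  expect_equal(effective_depth(60, 1.0), 60)
  expect_error(effective_depth(60, 1.5))
})

test_that("FASTQ output is deterministic and round-trips", {
  g <- generate_ancestor(5000, 1, 0.5, seed = 81)
  rs <- simulate_reads(g, "whole", 50, 0.01, depth = 2, seed = 82)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(rs, f1)
  rs_again <- simulate_reads(g, "whole", 50, 0.01, depth = 2, seed = 82)
  write_fastq(rs_again, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_fastq(f1)
  expect_identical(back$sequence, rs$sequence)
  expect_identical(back$read_id, rs$read_id)
  expect_identical(back$quality, rs$quality)
})
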