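# A small host/graft pair with a planted zero-divergence segment lets us
# exercise the false-positive mechanism (graft reads from conserved
# sequence) and the combined strategy's tie rule deterministically.
make_strategy_fixture <- function(seed = 301) {
  host <- generate_ancestor(20000, 1, 0.45, seed = seed, name = "human")
  ann <- annotate_genes(host, 4, seed = seed + 1)
  dv <- diverge(host, ann, divergence_spec(seed = seed + 2), name = "mouse")
  # plant an identical 300 bp segment in both genomes
  shared <- substr(host$seqs[[1]], 5001, 5300)
  gseq <- dv$genome$seqs[[1]]
  graft <- genome("mouse", c(chr1 = paste0(substr(gseq, 1, 9000), shared,
                                           substr(gseq, 9301, nchar(gseq)))))
  list(host = host, graft = graft,
       idx_h = build_index(host), idx_m = build_index(graft),
       idx_c = build_index(list(host, graft)))
}

fixture <- make_strategy_fixture()

test_that("direct mapping keeps host reads and leaks conserved-segment graft reads", {
  host_reads <- simulate_reads(fixture$host, "whole", 100, 0, depth = 0.5,
                               seed = 311)
  res <- run_direct(host_reads, fixture$idx_h)
  expect_identical(nrow(res$mouse), 0L)
  expect_gt(nrow(res$human) / nrow(host_reads), 0.99)
  # a graft read copied verbatim from the shared (host-identical) segment
  # aligns to the host reference: the false-positive mechanism
  leak <- hand_read("mouse", "chr1", 9050L, "+", 0L, 1L,
                    substr(fixture$graft$seqs[[1]], 9051, 9150))
  res2 <- run_direct(leak, fixture$idx_h)
  expect_identical(nrow(res2$human), 1L)
  # an unalignable random read ends up unaligned
  rnd <- hand_read("mouse", "chr1", 0L, "+", 0L, 2L,
                   paste(rep("ACGG", 25), collapse = ""))
  res3 <- run_direct(rnd, fixture$idx_h)
  expect_identical(length(res3$unaligned_ids), 1L)
})

test_that("filtering discards mouse-aligning reads and leaves the rest to the host", {
  graft_reads <- simulate_reads(fixture$graft, "whole", 100, 0, depth = 0.3,
                                seed = 321)
  host_reads <- simulate_reads(fixture$host, "whole", 100, 0, depth = 0.3,
                               seed = 322)
  mixed <- mix_reads(host_reads, graft_reads, c(1, 1), 100, seed = 323)
  res <- run_filtering(mixed, fixture$idx_m, fixture$idx_h)
  # graft reads from diverged sequence align only to the graft reference
  expect_gt(nrow(res$mouse), 0)
  tr <- parse_read_id(res$mouse$read_id)
  expect_gt(mean(tr$origin == "mouse"), 0.9)
  # a read aligning to neither genome is unaligned, not discarded
  rnd <- hand_read("mouse", "chr1", 0L, "+", 0L, 99L,
                   paste(rep("ACGG", 25), collapse = ""))
  res2 <- run_filtering(rnd, fixture$idx_m, fixture$idx_h)
  expect_identical(res2$unaligned_ids, rnd$read_id)
  expect_identical(nrow(res2$mouse), 0L)
})

test_that("combined mapping assigns by unique best genome and ties go unaligned", {
  # strictly-best on host: a host read from diverged (non-shared) sequence
  host_read <- hand_read("human", "chr1", 1000L, "+", 0L, 1L,
                         substr(fixture$host$seqs[[1]], 1001, 1100))
  res <- run_combined(host_read, index = fixture$idx_c, human_name = "human")
  expect_identical(nrow(res$human), 1L)
  # a read from the shared segment scores identically in both genomes: tie
  tie <- hand_read("human", "chr1", 5000L, "+", 0L, 2L,
                   substr(fixture$host$seqs[[1]], 5001, 5100))
  res2 <- run_combined(tie, index = fixture$idx_c, human_name = "human")
  expect_identical(res2$unaligned_ids, tie$read_id)
})

test_that("the three sets partition the input and subset laws hold", {
  host_reads <- simulate_reads(fixture$host, "whole", 100, 1e-3, depth = 1,
                               seed = 331)
  graft_reads <- simulate_reads(fixture$graft, "whole", 100, 1e-3, depth = 1,
                                seed = 332)
  mixed <- mix_reads(host_reads, graft_reads, c(1, 1), 300, seed = 333)
  ids <- sort(mixed$read_id)
  results <- list(
    run_direct(mixed, fixture$idx_h),
    run_filtering(mixed, fixture$idx_m, fixture$idx_h),
    run_combined(mixed, index = fixture$idx_c, human_name = "human"))
  for (res in results) {
    got <- sort(c(res$human$read_id, res$mouse$read_id, res$unaligned_ids))
    expect_identical(got, ids)  # exact partition
  }
  direct_ids <- results[[1]]$human$read_id
  expect_true(all(results[[2]]$human$read_id %in% direct_ids))
  expect_true(all(results[[3]]$human$read_id %in% direct_ids))
})

test_that("contamination estimates reproduce the published worked examples", {
  # C15 xenograft: combined, direct, filtering
  expect_equal(round(100 * estimate_contamination(676132399, 1784069633), 1), 27.5)
  expect_equal(round(100 * estimate_contamination(681133817, 1786870566), 1), 27.6)
  expect_equal(round(100 * estimate_contamination(681133817, 1768136467), 1), 27.8)
  # C666-1 cell line (expected contamination-free)
  expect_equal(round(100 * estimate_contamination(6121700, 2399396153), 2), 0.25)
  expect_equal(round(100 * estimate_contamination(6121700, 2392763986), 2), 0.26)
  expect_equal(round(100 * estimate_contamination(346213, 2340660573), 2), 0.01)
})

test_that("contamination estimator handles edge cases", {
  expect_equal(estimate_contamination(0, 1000), 0)
  expect_equal(estimate_contamination(1000, 0), 1)
  expect_warning(est <- estimate_contamination(0, 0), "undefined")
  expect_true(is.na(est))
  expect_error(estimate_contamination(-1, 5), "non-negative")
})

test_that("strategy results export as SAM plus an unaligned list", {
  host_reads <- simulate_reads(fixture$host, "whole", 100, 0, depth = 0.2,
                               seed = 341)
  res <- run_direct(host_reads, fixture$idx_h)
  dir <- file.path(tempdir(), "strategy-export")
  export_strategy_result(res, host_reads, fixture$idx_h, dir)
  sam <- file.path(dir, "direct_human.sam")
  expect_true(file.exists(sam))
  back <- ingest_sam(sam, fixture$idx_h)
  expect_setequal(back$read_id, res$human$read_id)
  expect_true(file.exists(file.path(dir, "direct_unaligned.txt")))
})
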