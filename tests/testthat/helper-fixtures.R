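# Shared fixtures, all generated in code.

# Small forged genome pair with annotations, memoised per test file run.
make_pair <- function(length = 5e4, n_genes = 8, seed = 101,
                      div = divergence_spec(seed = seed + 2)) {
  host <- generate_ancestor(length, 2, 0.45, seed = seed, name = "human")
  ann <- annotate_genes(host, n_genes, seed = seed + 1)
  dv <- diverge(host, ann, div, name = "mouse")
  list(host = host, ann = ann, graft = dv$genome, maps = dv$maps)
}

# Independent replay of a truth table onto a reference chromosome: applies
# events right-to-left with plain string surgery. Used as the oracle for
# mutate_genome.
replay_truth <- function(seq, truth_chrom) {
  t <- truth_chrom[order(-truth_chrom$pos), , drop = FALSE]
  for (i in seq_len(nrow(t))) {
    p <- t$pos[i]  # 0-based
    if (t$vtype[i] == "SNV") {
      stopifnot(substr(seq, p + 1, p + 1) == t$ref_allele[i])
      substr(seq, p + 1, p + 1) <- t$alt_allele[i]
    } else if (t$vtype[i] == "DEL") {
      w <- nchar(t$ref_allele[i])
      stopifnot(substr(seq, p + 1, p + w) == t$ref_allele[i])
      seq <- paste0(substr(seq, 1, p), substr(seq, p + w + 1, nchar(seq)))
    } else {  # INS before position p
      seq <- paste0(substr(seq, 1, p), t$alt_allele[i],
                    substr(seq, p + 1, nchar(seq)))
    }
  }
  seq
}

# 99% two-sided binomial acceptance interval for an observed count.
binom99 <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p)

expect_within_binom99 <- function(count, n, p) {
  iv <- binom99(n, p)
  expect_gte(count, iv[1])
  expect_lte(count, iv[2])
}

# A read_set row built by hand (for strategy/evaluate fixtures).
hand_read <- function(origin, chrom, start, strand, n_err, serial, seq,
                      qual = 40L) {
  data.frame(
    read_id = sprintf("%s_%s_%d_%s_%d_%d", origin, chrom, start, strand,
                      n_err, serial),
    sequence = seq, quality = qual, origin = origin, chrom = chrom,
    start = start, strand = strand, n_err = n_err, stringsAsFactors = FALSE)
}
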