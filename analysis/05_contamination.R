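#!/usr/bin/env Rscript
# Contamination-rate estimation. First the simulation check: the combined
# strategy's mouse-aligned fraction should recover the true mixing fraction
# at both 10% and 50% contamination. Then the published worked examples:
# per-strategy alignment counts for the C15 xenograft and the C666-1 cell
# line, where the same arithmetic gives ~27.5% and ~0% mouse DNA.

suppressPackageStartupMessages(library(xenosim))
dir.create("results", showWarnings = FALSE)

rows <- list()
for (ratio in c("9:1", "1:1")) {
  st <- run_study(study_config(profile = "mH.len100.eL", regions = "all",
                               ratio = ratio, strategies = "combined",
                               baseline = FALSE, seed = 1))
  est <- st$contamination[st$contamination$strategy == "combined", ]
  rows[[ratio]] <- data.frame(source = "simulation", sample = ratio,
                              strategy = "combined",
                              estimated_pct = round(100 * est$estimated, 2),
                              true_pct = 100 * est$true_fraction)
}

worked <- data.frame(
  sample = rep(c("C15", "C666-1"), each = 3),
  strategy = rep(c("direct", "filtering", "combined"), 2),
  mouse = c(681133817, 681133817, 676132399, 6121700, 6121700, 346213),
  human = c(1786870566, 1768136467, 1784069633,
            2399396153, 2392763986, 2340660573))
worked$estimated_pct <- mapply(function(m, h, d)
  round(100 * estimate_contamination(m, h), d),
  worked$mouse, worked$human, rep(c(1, 2), each = 3))
rows[["worked"]] <- data.frame(source = "published_counts",
                               sample = worked$sample,
                               strategy = worked$strategy,
                               estimated_pct = worked$estimated_pct,
                               true_pct = NA)

tab <- do.call(rbind, rows)
write.table(tab, "results/05_contamination.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Contamination estimates\n")
print(tab, row.names = FALSE)
cat("\nC15 (xenograft) estimates cluster near 27.5-27.8%; C666-1 (pure\n")
cat("cell line) near zero, with the combined reference giving the\n")
cat("cleanest near-zero value (0.01%).\n")
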