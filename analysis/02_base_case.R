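#!/usr/bin/env Rscript
# The base case: profile mH.len100.eL (1% mutation, 100 bp reads, 0.01%
# error), 1:1 host:graft mixing, reads from everywhere, 60x total. Runs all
# three handling strategies plus the no-contamination control and reports
# FDR/FNR at the alignment, variant and non-synonymous-SNV levels, plus the
# non-synonymous false-positive/false-negative counts per strategy.

suppressPackageStartupMessages(library(xenosim))
dir.create("results", showWarnings = FALSE)

st <- run_study(study_config(profile = "mH.len100.eL", regions = "all",
                             ratio = "1:1", total_depth = 60, seed = 1),
                verbose = TRUE)

write.table(st$report, "results/02_base_case_accuracy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ns <- st$report[st$report$level == "nonsynonymous",
                c("strategy", "fp", "fn")]
names(ns) <- c("strategy", "false_positive_nonsyn_snvs",
               "false_negative_nonsyn_snvs")
write.table(ns, "results/02_nonsynonymous_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nAccuracy by strategy and level (base case)\n")
print(st$report, digits = 4, row.names = FALSE)
cat("\nNon-synonymous SNV errors\n")
print(ns, row.names = FALSE)
cat("\nReading: the filtering and combined strategies hold alignment and\n",
    "variant FDR near the no-contamination control, while direct mapping\n",
    "pays a large false-discovery penalty; the combined reference keeps\n",
    "the variant FNR at or below filtering's.\n", sep = "")
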