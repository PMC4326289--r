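#!/usr/bin/env Rscript
# Forge the default host/graft surrogate genome pair, generate the base-case
# read mixture (profile mH.len100.eL, 1:1 host:graft, whole-genome regions,
# 60x), and record what the simulated data look like. Large artifacts
# (FASTA/FASTQ/BED) go under scratch/analysis/; the summary table under
# results/.

suppressPackageStartupMessages(library(xenosim))

out_big <- "scratch/analysis/base_case"
dir.create(out_big, showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

seed <- 1L
host <- generate_ancestor(5e5, 2, gc_fraction = 0.45, seed = seed + 1, name = "human")
ann <- annotate_genes(host, 50, seed = seed + 2)
dv <- diverge(host, ann, divergence_spec(seed = seed + 3), name = "mouse")

write_genome_fasta(host, file.path(out_big, "host_ref.fasta"))
write_genome_fasta(dv$genome, file.path(out_big, "graft_ref.fasta"))
write_bed(ann$exome, file.path(out_big, "exome.bed"))
write_gene_table(ann$genes, file.path(out_big, "genes.tsv"))

# measured divergence between the two references (substitutions only count
# toward identity inside alignment columns; here we report the per-event
# totals the forge actually applied)
exome_bases <- sum(ann$exome$end - ann$exome$start)
prof <- sim_profile("mH.len100.eL")
mut_h <- mutate_genome(host, prof$mutation_rate, seed = seed + 4)
mut_g <- mutate_genome(dv$genome, prof$mutation_rate, seed = seed + 5)
h <- simulate_reads(mut_h$genome, "whole", prof$read_length, prof$error_rate,
                    depth = 33, seed = seed + 6, coord_map = mut_h$maps)
g <- simulate_reads(mut_g$genome, "whole", prof$read_length, prof$error_rate,
                    depth = 33, seed = seed + 7, coord_map = mut_g$maps)
n_total <- round(60 * sum(genome_lengths(host)) / prof$read_length)
mixed <- mix_reads(h, g, c(1, 1), n_total, seed = seed + 8)
write_fastq(mixed, file.path(out_big, "reads.fastq"))
write_variant_truth(mut_h$truth, file.path(out_big, "truth_variants.tsv"))

summary <- data.frame(
  quantity = c("host_genome_bases", "host_chromosomes", "genes",
               "exome_bases", "exome_fraction", "graft_substitutions",
               "graft_indels", "host_truth_snvs", "host_truth_indels",
               "read_length", "total_reads", "host_reads", "graft_reads",
               "effective_host_depth", "effective_graft_depth"),
  value = c(sum(genome_lengths(host)), length(host$seqs), 50, exome_bases,
            round(exome_bases / sum(genome_lengths(host)), 4),
            dv$n_events[["substitutions"]], dv$n_events[["indels"]],
            sum(mut_h$truth$vtype == "SNV"), sum(mut_h$truth$vtype != "SNV"),
            prof$read_length, nrow(mixed), sum(mixed$origin == "human"),
            sum(mixed$origin == "mouse"),
            effective_depth(60, 0.5), effective_depth(60, 0.5)))
write.table(summary, "results/01_simulation_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Base-case simulated data set\n")
print(summary, row.names = FALSE)
cat("\nArtifacts in", out_big, "- summary in results/01_simulation_summary.tsv\n")
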