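Package: xenosim
Title: Simulation-Based Benchmarking of Read-Handling Strategies for
    Mouse-Contaminated Xenograft Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how contaminating mouse reads in patient-derived
    xenograft (PDX) DNA sequencing affect read alignment and variant calling.
    Provides a synthetic-genome forge that emulates the human/mouse divergence
    structure (conserved exons, divergent intergenic sequence), a ground-truth
    read simulator with configurable mutation, read-length and sequencing-error
    profiles, a compiled seed-and-extend aligner with unique-best-match
    semantics, the three canonical contamination-handling strategies (direct
    mapping, mouse-filtering, combined reference), a pileup-based diploid SNV
    caller with Phred-scaled qualities, truth-based FDR/FNR scoring at the
    alignment, variant and non-synonymous-SNV levels, and an alignment-count
    estimator of the mouse contamination fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
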