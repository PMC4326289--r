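---
title: "Simulating mouse contamination in xenograft sequencing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mouse contamination in xenograft sequencing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(xenosim)
```

## The problem

DNA sequenced from a patient-derived xenograft (PDX) is a mixture: human
tumor reads plus reads from the mouse stroma that replaced the human stroma
during engraftment. Because the human and mouse genomes are similar —
especially in coding sequence, where identity is around 85% — a mouse read
can align convincingly to the human reference, and its systematic
mismatches then masquerade as somatic variants. Three handling strategies
are in common use:

* **direct mapping** — align everything to the human reference and hope the
  contamination does not matter;
* **filtering** — align to the mouse reference first, discard whatever
  aligns, then map the remainder to the human reference;
* **combined reference** — align once against a human+mouse union and
  assign each read to the genome holding its *unique best* locus, leaving
  cross-genome ties unaligned.

`xenosim` rebuilds this comparison as a fully seeded desk-scale simulation:
every read and every planted variant carries ground truth, so alignment and
variant-calling accuracy can be scored exactly, as false discovery rate
FDR = FP/(FP+TP) and false negative rate FNR = FN/(FN+TP).

## The synthetic genome pair

Real chromosome-scale references make the comparison slow and irreproducible
at the desk; instead the package forges a surrogate pair whose *statistical*
structure drives the same phenomena:

* `generate_ancestor()` draws an i.i.d. host genome — default 500 kb over 2
  chromosomes at GC 0.45. This length leaves thousands of planted SNVs and
  hundreds of thousands of reads per run, enough for stable FDR/FNR
  estimates, while a full strategy comparison stays in the minutes range.
* `annotate_genes()` places ~50 non-overlapping multi-exon gene models
  (CDS length ≈ N(1500, 400²) rounded to a codon multiple, 1–4 exons,
  geometric introns), covering ~15% of the genome — a deliberately
  exome-dense surrogate so exome-mode runs retain enough reads.
* `diverge()` derives the graft ("mouse") reference by substituting each
  base with probability **0.15 inside exons** and **0.35 outside**, plus
  indels at 0.02 per base with geometric lengths (mean 2). The exonic rate
  reproduces the ~85% coding identity between the real genomes; the
  non-exonic rate and indel load are not published quantities, so they were
  chosen once such that 50–100 bp reads from one genome only occasionally
  align to the other — the ambiguity regime that makes the strategy choice
  interesting. They are exposed in `divergence_spec()` but the defaults are
  the study conditions.

Coordinates are 0-based half-open everywhere inside the package; 1-based
conventions appear only at the SAM and VCF boundaries. Every edit operation
returns a coordinate map so intervals and read positions can be lifted
between a reference and its derived genome (`lift_intervals()`); positions
inside an indel snap to its boundary, which is why alignment scoring uses a
positional tolerance (below).

What the forge does **not** emulate: repeat families, segmental
duplications, GC isochores, synteny, and paired-end structure. Passing
results therefore demonstrate the logic of the strategy comparison under
divergence-driven ambiguity, not performance on repeat-rich real genomes,
where multi-mapping adds failure modes the surrogate lacks by construction.

## Sample genomes and reads

`mutate_genome()` turns each reference into a "sample" genome: each base
mutates independently with the profile's mutation rate; a mutation is an
SNV with probability 0.9, otherwise an indel (insertion or deletion with
equal probability, geometric length, mean 2 — the 9:1 SNV:indel split).
Truth records live in reference coordinates. Whether the original study's
indels were single-base is not documented; the length distribution is a
knob (`indel_length_mean`) with the geometric default.

`simulate_reads()` draws `round(depth × region_length / read_length)`
single-end reads uniformly from the requested regions (whole genome or
exome), uniform strand, then flips each base to a different uniformly
chosen base with the profile's error probability. All bases carry the flat
Phred quality `min(40, round(−10·log10(error_rate)))`; 40 is the cap when a
zero error rate is requested. Platform-specific artifacts (quality decay
along the read, homopolymer errors) are out of scope. Read identifiers
encode the truth tuple (origin genome, chromosome, start, strand, planted
errors) in an underscore-joined convention so external aligner output
remains scoreable.

The eight parameter profiles cross mutation rate {0, 0.01}, read length
{50, 100} and error rate {0.0001, 0.01}; with two mixing ratios (9:1, 1:1)
and two region modes that is the 32-configuration grid of
`enumerate_datasets()`. A 60× mixture at 9:1 carries an effective 54× of
host data (`effective_depth(60, 0.9)`), at 1:1 30×; the depth-scheme runs
add a doubled 60×:60× design.

## The aligner

The built-in aligner substitutes for a production short-read mapper at desk
scale and is the one place the package uses compiled code. It is
seed-and-extend: k-mers (default k = 15) sampled every ⌊read_length/4⌋
bases (plus one flush with the read end) are looked up in a hash index over
all chromosomes of all registered genomes — chromosomes are namespaced
`<genome>:<chrom>`, which is what makes the combined-reference strategy a
union index rather than a concatenated FASTA (semantically identical, and
irrelevant at these genome sizes). Each candidate diagonal is extended by a
fitting alignment — global in the read, free reference flanks — over a
window of ± `band` (default 8) around the diagonal, with affine gaps.
Scoring defaults are match +1, mismatch −2, gap open −4, gap extend −1; any
consistent scheme works since only score comparisons matter.

Numerical/tie rules, stated explicitly because they are load-bearing:

* If the best score is attained at more than one distinct locus
  (chromosome, strand, leftmost position), the read is returned
  `mapped = FALSE`, `unique = FALSE`, `mapq = 0`. This is the
  unique-best-match rule; in the combined strategy it is what sends
  conserved-segment reads to the unaligned pile instead of guessing.
* Otherwise `mapq = min(60, 2 × (best − second_best))`; only the
  zero/non-zero distinction is relied upon downstream.
* "Successfully aligned" means mapped, unique, and score ≥
  ⌊0.6 × read_length × match⌋ — an identity floor playing the role of a
  production aligner's default sensitivity. It is the filtering strategy's
  default discard criterion (the original study says only "a high alignment
  score"); a stricter absolute cutoff can be supplied.
* Traceback prefers diagonal over read-gap over reference-gap, making
  CIGARs deterministic.

Correctness is checked against an exhaustive oracle (`oracle_align()`):
an unrestricted fitting DP scanning every position of every chromosome on
both strands, with optimal start positions recovered by running the DP on
reversed sequences. The test suite requires exact agreement of best score,
tie status and locus on hundreds of randomized ≤1 kb instances. The oracle
is quadratic and independent of the seeding path; it never substitutes for
the aligner in the pipeline.

Reproducing mapper-specific differences (the original comparison found the
combined strategy's FNR depended on which production aligner was used) is
explicitly out of scope; `ingest_sam()` exists so a real aligner's primary
records can be scored instead, provided read names follow the truth codec.

## Variant calling

`pileup()` accumulates per-position base counts (and per-base-class mean
qualities) from mapped, unique alignments; insertions contribute nothing,
deletions leave a coverage gap. `call_snvs()` applies the simplest genotype
model consistent with using a standard caller at defaults: independent
observations, diploid genotypes {ref/ref, ref/alt, alt/alt} with a uniform
prior, alt = the most frequent non-reference base (ties broken
alphabetically), per-observation error from the base quality. The call
quality is −10·log10 P(ref/ref | data), computed in log space; calls need
depth ≥ 3 and survive `filter_calls()` at QUAL ≥ 13 — the conventional
default, an error probability of 10^−1.3 = 0.05012. Because simulated
qualities are flat, using the per-base-class mean quality is exact. This
caller is a documented stand-in, not a reimplementation of any production
caller, and indel calling is deliberately absent: evaluation is SNV-level
throughout, matching the study design.

## Scoring rules

Alignment level: a host read is a true positive when aligned to the host
reference on the truth chromosome and strand within `pos_tolerance`
(default 5 bp — indels shift leftmost coordinates and lifted truth
positions snap to indel boundaries). A host read aligned to the *wrong*
place is counted both as FP (it is an incorrect alignment) and as FN (the
read is not correctly aligned); the published definitions admit either
reading and the double count is the conservative one, so it is fixed here
as policy. Graft reads aligned to the host reference are FPs.

Variant level: calls match truth on (chromosome, position, alt allele) —
requiring the allele avoids inflating TP by coincidental positions. The
non-synonymous level re-scores the variant-level sets after codon-aware
effect classification (strand-aware, frame anchored at the CDS start,
standard genetic code).

The FDR/FNR formulas above are the standard ones; the source text of the
study renders its formulas illegibly, but its prose descriptions match
these definitions exactly.

## The study runner and problem sizes

`run_study()` chains the stages under a single master seed (each stage
derives `seed + k` for a fixed small k, so runs are reproducible and
stages independently re-runnable). The no-contamination control simulates
host-only reads at the host's effective depth — the natural reading of the
original design, exposed as `host_depth` for sensitivity checks. In exome
mode reads are drawn from exome intervals only but alignment is
unrestricted, matching the study's setup.

Problem sizes used by the shipped analyses and tests: the default surrogate
(500 kb, 60×, ~300,000 reads at 1:1) for the headline comparisons,
contamination recovery and depth schemes; a 0.2-scaled surrogate for the
eight-profile sweep; ≤1 kb instances for the oracle-equivalence suite.
These were chosen so the complete test suite and all analysis drivers run
in well under an hour on a single core.

## Known limitations

* The surrogate genomes are repeat-free, so multi-mapping ambiguity is
  driven entirely by host–graft homology; absolute FDR/FNR values are not
  comparable to chromosome-scale runs, only the orderings and mechanisms.
* The caller's independence assumptions understate linkage between
  neighboring divergent sites on the same leaked graft read; this makes the
  direct strategy's false calls, if anything, easier to produce — the
  mechanism under study.
* Contamination estimation from alignment counts inherits each strategy's
  biases (the filtering estimate uses the all-reads-to-mouse count; the
  direct estimate requires that companion run).
* Single-end reads only; paired-end rescue would reduce every strategy's
  ambiguity in ways the package does not model.

## Interfaces

The package is organised as a library plus numbered analysis drivers under
`analysis/` (simulation summary, base case, exome vs whole, depth schemes,
contamination, profile sweep), each a thin narrative script over exported
functions that writes its tables under `results/`. Standard formats are
supported at every boundary — FASTA/BED/FASTQ in, SAM/VCF/TSV out — so any
stage can be swapped for external tooling.
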