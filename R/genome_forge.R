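#' Generate a random ancestral genome
#'
#' Draws i.i.d. bases with the requested GC content, split into
#' `n_chromosomes` chromosomes of (near-)equal length. This ancestor plays
#' the role of the host ("human") reference; [diverge()] derives the related
#' graft ("mouse") reference from it.
#'
#' @param total_length total number of bases across chromosomes.
#' @param n_chromosomes number of chromosomes.
#' @param gc_fraction probability that a base is G or C.
#' @param seed integer seed; identical inputs give byte-identical genomes.
#' @param name genome identifier.
#' @return an `xeno_genome`.
#' @export
generate_ancestor <- function(total_length, n_chromosomes, gc_fraction = 0.5,
                              seed = 1L, name = "human") {
  stopifnot(is.numeric(total_length), length(total_length) == 1L,
            is.numeric(n_chromosomes), length(n_chromosomes) == 1L)
  if (total_length < 0 || n_chromosomes < 0)
    stop("total_length and n_chromosomes must be non-negative")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]")
  if (n_chromosomes == 0) {
    if (total_length > 0) stop("cannot place bases on zero chromosomes")
    return(genome(name, character(0)))
  }
  if (total_length == 0)
    stop("total_length must be positive when n_chromosomes > 0 (empty chromosomes are not allowed)")
  lens <- rep(total_length %/% n_chromosomes, n_chromosomes)
  lens[1] <- lens[1] + total_length %% n_chromosomes
  seqs <- with_seed(seed, {
    vapply(lens, function(L) paste(random_bases(L, gc_fraction), collapse = ""), "")
  })
  names(seqs) <- paste0("chr", seq_len(n_chromosomes))
  genome(name, seqs)
}

#' Annotate a genome with protein-coding gene models
#'
#' Places non-overlapping multi-exon gene models on both strands. Each gene's
#' total CDS length is a multiple of 3 (the reading frame is anchored at the
#' CDS start and runs across exons). The union of CDS intervals is returned
#' as the exome.
#'
#' @param g an `xeno_genome`.
#' @param n_genes number of genes to place.
#' @param cds_length_distribution list with elements `mean_cds`, `sd_cds`,
#'   `min_cds` (bases), `max_exons`, `intron_mean` (bases).
#' @param seed integer seed.
#' @return list with `genes` (data frame: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `exon_rank`; one row per CDS interval, 0-based
#'   half-open) and `exome` (merged `chrom`/`start`/`end` intervals).
#' @export
annotate_genes <- function(g, n_genes,
                           cds_length_distribution = list(
                             mean_cds = 1500, sd_cds = 400, min_cds = 150,
                             max_exons = 4, intron_mean = 300),
                           seed = 1L) {
  stopifnot(inherits(g, "xeno_genome"))
  empty <- list(
    genes = data.frame(gene_id = character(), chrom = character(),
                       strand = character(), start = integer(),
                       end = integer(), exon_rank = integer(),
                       stringsAsFactors = FALSE),
    exome = data.frame(chrom = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE))
  if (n_genes == 0) return(empty)
  if (length(g$seqs) == 0) stop("cannot annotate an empty genome")
  d <- cds_length_distribution
  lens <- genome_lengths(g)
  with_seed(seed, {
    occupied <- lapply(names(lens), function(ch) matrix(numeric(0), ncol = 2))
    names(occupied) <- names(lens)
    rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      # total CDS length: multiple of 3, at least min_cds
      L <- max(d$min_cds, round(rnorm(1, d$mean_cds, d$sd_cds)))
      L <- 3L * as.integer(ceiling(L / 3))
      k <- sample.int(d$max_exons, 1)
      # split L into k exon lengths, each at least 12 bases
      cuts <- if (k > 1) sort(sample.int(L - 12L * k, k - 1L, replace = TRUE)) else integer(0)
      exon_len <- diff(c(0L, cuts, L - 12L * k)) + 12L
      intron_len <- if (k > 1) rgeom(k - 1L, 1 / d$intron_mean) + 20L else integer(0)
      span <- sum(exon_len) + sum(intron_len)
      strand <- sample(c("+", "-"), 1)
      placed <- FALSE
      for (try in 1:200) {
        ch <- sample(names(lens), 1, prob = lens)
        if (lens[[ch]] < span + 2) next
        s0 <- sample.int(lens[[ch]] - span, 1) - 1L
        occ <- occupied[[ch]]
        if (nrow(occ) == 0 || all(s0 + span <= occ[, 1] | s0 >= occ[, 2])) {
          occupied[[ch]] <- rbind(occ, c(s0, s0 + span))
          starts <- s0 + cumsum(c(0L, head(exon_len, -1) + intron_len))
          rows[[i]] <- data.frame(
            gene_id = sprintf("gene%04d", i), chrom = ch, strand = strand,
            start = as.integer(starts), end = as.integer(starts + exon_len),
            exon_rank = seq_len(k), stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", n_genes, " non-overlapping genes; genome too short")
    }
    genes <- do.call(rbind, rows)
    rownames(genes) <- NULL
    list(genes = genes,
         exome = merge_intervals(genes[, c("chrom", "start", "end")]))
  })
}

#' Divergence parameters for deriving the graft reference
#'
#' Region-aware substitution rates emulate the conservation contrast between
#' coding and non-coding sequence: mammalian coding sequence stays far more
#' similar between host and graft species (~85% identity at the default
#' exonic rate of 0.15) than intergenic/intronic sequence does.
#'
#' @param exonic_substitution_rate per-base substitution probability inside
#'   exome intervals. Default 0.15 (85% coding identity).
#' @param nonexonic_substitution_rate per-base substitution probability
#'   elsewhere; must be at least the exonic rate. Default 0.35.
#' @param indel_rate per-base indel initiation probability. Default 0.02.
#' @param indel_length_mean mean indel length (geometric, minimum 1).
#' @param seed integer seed.
#' @return a list of class `divergence_spec`.
#' @export
divergence_spec <- function(exonic_substitution_rate = 0.15,
                            nonexonic_substitution_rate = 0.35,
                            indel_rate = 0.02, indel_length_mean = 2,
                            seed = 1L) {
  rates <- c(exonic_substitution_rate, nonexonic_substitution_rate, indel_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (nonexonic_substitution_rate < exonic_substitution_rate)
    stop("nonexonic_substitution_rate must be >= exonic_substitution_rate (exons are conserved)")
  if (indel_length_mean < 1) stop("indel_length_mean must be >= 1")
  structure(list(exonic_substitution_rate = exonic_substitution_rate,
                 nonexonic_substitution_rate = nonexonic_substitution_rate,
                 indel_rate = indel_rate, indel_length_mean = indel_length_mean,
                 seed = seed),
            class = "divergence_spec")
}

# --- sequence edit engine ---------------------------------------------------
#
# Events are given in 0-based source coordinates:
#   SNV: replace 1 base at pos with `alt`
#   DEL: remove `len` bases starting at pos
#   INS: insert `alt` before pos
# SNVs never shift coordinates and are applied vectorized; indels are applied
# left to right, skipping any event falling inside an earlier deletion.
# Returns the edited sequence, the applied events (with reference alleles
# filled in), and a coordinate map between source and derived positions.
edit_sequence <- function(seq, snv_pos, snv_alt, indels) {
  n <- nchar(seq)
  if (length(snv_pos) > 0) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    snv_ref <- chars[snv_pos + 1L]
    chars[snv_pos + 1L] <- snv_alt
    seq <- paste(chars, collapse = "")
  } else {
    snv_ref <- character(0)
  }
  map <- data.frame(ref_at = numeric(0), der_at = numeric(0), off = numeric(0))
  applied <- NULL
  if (!is.null(indels) && nrow(indels) > 0) {
    indels <- indels[order(indels$pos), , drop = FALSE]
    pieces <- character(0)
    cursor <- 0L  # source position consumed so far
    off <- 0L
    keep <- logical(nrow(indels))
    ref_allele <- character(nrow(indels))
    maps <- vector("list", nrow(indels))
    for (e in seq_len(nrow(indels))) {
      p <- indels$pos[e]
      if (p < cursor || p >= n) next
      keep[e] <- TRUE
      pieces <- c(pieces, substr(seq, cursor + 1L, p))
      if (indels$type[e] == "DEL") {
        len <- min(indels$len[e], n - p)
        ref_allele[e] <- substr(seq, p + 1L, p + len)
        cursor <- p + len
        off <- off - len
      } else {  # INS
        pieces <- c(pieces, indels$alt[e])
        ref_allele[e] <- ""
        cursor <- p
        off <- off + nchar(indels$alt[e])
      }
      maps[[e]] <- c(ref_at = cursor, der_at = cursor + off, off = off)
    }
    pieces <- c(pieces, substr(seq, cursor + 1L, n))
    seq <- paste(pieces, collapse = "")
    applied <- indels[keep, , drop = FALSE]
    applied$ref_allele <- ref_allele[keep]
    if (any(keep))
      map <- as.data.frame(do.call(rbind, maps[keep]))
  }
  list(seq = seq,
       snv = data.frame(pos = snv_pos, ref_allele = snv_ref, alt_allele = snv_alt,
                        stringsAsFactors = FALSE),
       indels = applied, map = map)
}

# Map positions across an edit. `map` is the per-chromosome table produced by
# edit_sequence; direction "ref2der" maps source -> derived, "der2ref" the
# inverse. Positions inside an indel map to its boundary (nearest preserved
# coordinate).
map_positions <- function(pos, map, direction = c("ref2der", "der2ref")) {
  direction <- match.arg(direction)
  if (is.null(map) || nrow(map) == 0) return(pos)
  key <- if (direction == "ref2der") map$ref_at else map$der_at
  idx <- findInterval(pos, key)
  off <- c(0, map$off)[idx + 1L]
  if (direction == "ref2der") pos + off else pos - off
}

#' Lift intervals through a coordinate map
#'
#' @param iv data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param maps named list of per-chromosome coordinate maps, as returned in
#'   the `maps` element of [diverge()] or [mutate_genome()].
#' @param direction `"ref2der"` (source to derived genome) or `"der2ref"`.
#' @return the lifted intervals (degenerate intervals dropped).
#' @export
lift_intervals <- function(iv, maps, direction = "ref2der") {
  if (nrow(iv) == 0) return(iv)
  out <- iv
  for (ch in unique(iv$chrom)) {
    sel <- iv$chrom == ch
    m <- maps[[ch]]
    out$start[sel] <- map_positions(iv$start[sel], m, direction)
    out$end[sel] <- map_positions(iv$end[sel], m, direction)
  }
  out[out$end > out$start, , drop = FALSE]
}

#' Derive a diverged (graft) genome from an ancestor
#'
#' Applies per-base substitutions at region-dependent rates (lower inside
#' the exome) and indels at a uniform rate, producing the graft-species
#' reference surrogate. Deterministic given the spec's seed.
#'
#' @param ancestor an `xeno_genome` (the host reference).
#' @param annotations the list returned by [annotate_genes()], or a plain
#'   `chrom`/`start`/`end` exome data frame.
#' @param spec a [divergence_spec()].
#' @param name name for the derived genome.
#' @return list with `genome` (the diverged `xeno_genome`), `maps` (named
#'   per-chromosome coordinate maps; see [lift_intervals()]) and `n_events`
#'   (substitution/indel counts).
#' @export
diverge <- function(ancestor, annotations, spec = divergence_spec(),
                    name = "mouse") {
  stopifnot(inherits(ancestor, "xeno_genome"), inherits(spec, "divergence_spec"))
  exome <- if (is.data.frame(annotations)) annotations else annotations$exome
  with_seed(spec$seed, {
    seqs <- character(length(ancestor$seqs))
    names(seqs) <- names(ancestor$seqs)
    maps <- vector("list", length(seqs))
    names(maps) <- names(seqs)
    n_sub <- 0L
    n_indel <- 0L
    for (ch in names(ancestor$seqs)) {
      s <- ancestor$seqs[[ch]]
      L <- nchar(s)
      rate <- rep(spec$nonexonic_substitution_rate, L)
      ex <- exome[exome$chrom == ch, , drop = FALSE]
      for (r in seq_len(nrow(ex)))
        rate[(ex$start[r] + 1L):ex$end[r]] <- spec$exonic_substitution_rate
      sub_pos <- which(runif(L) < rate) - 1L
      ind_pos <- if (spec$indel_rate > 0) which(runif(L) < spec$indel_rate) - 1L else integer(0)
      sub_pos <- setdiff(sub_pos, ind_pos)  # indels take precedence at a base
      chars <- if (length(sub_pos)) substring(s, sub_pos + 1L, sub_pos + 1L)
               else character(0)
      alt <- substitute_bases(chars)
      indels <- NULL
      if (length(ind_pos) > 0) {
        type <- sample(c("INS", "DEL"), length(ind_pos), replace = TRUE)
        len <- rgeom(length(ind_pos), 1 / spec$indel_length_mean) + 1L
        alt_ins <- vapply(len, function(l) paste(sample(DNA_BASES, l, replace = TRUE),
                                                 collapse = ""), "")
        indels <- data.frame(pos = ind_pos, type = type, len = len,
                             alt = ifelse(type == "INS", alt_ins, ""),
                             stringsAsFactors = FALSE)
      }
      ed <- edit_sequence(s, sub_pos, alt, indels)
      seqs[[ch]] <- ed$seq
      maps[[ch]] <- ed$map
      n_sub <- n_sub + length(sub_pos)
      n_indel <- n_indel + if (is.null(ed$indels)) 0L else nrow(ed$indels)
    }
    list(genome = genome(name, seqs), maps = maps,
         n_events = c(substitutions = n_sub, indels = n_indel))
  })
}

# Replace each base with one of the other three, uniformly.
substitute_bases <- function(chars) {
  if (length(chars) == 0) return(character(0))
  cur <- match(chars, DNA_BASES)
  DNA_BASES[((cur - 1L + sample.int(3L, length(chars), replace = TRUE)) %% 4L) + 1L]
}

#' Write / read a gene-model table
#'
#' Plain-text representation: one row per gene with comma-separated CDS
#' intervals (`start-end`, 0-based half-open).
#'
#' @param genes the per-interval gene data frame from [annotate_genes()].
#' @param path output path.
#' @return `write_gene_table()` returns `path` invisibly; `read_gene_table()`
#'   the per-interval data frame.
#' @export
write_gene_table <- function(genes, path) {
  by_gene <- split(genes, genes$gene_id)
  rows <- vapply(by_gene, function(d) {
    d <- d[order(d$exon_rank), ]
    paste(d$gene_id[1], d$chrom[1], d$strand[1],
          paste(sprintf("%d-%d", d$start, d$end), collapse = ","), sep = "\t")
  }, "")
  writeLines(c("gene_id\tchrom\tstrand\tcds_intervals", rows), path)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    parts <- strsplit(strsplit(d$cds_intervals[i], ",")[[1]], "-")
    data.frame(gene_id = d$gene_id[i], chrom = d$chrom[i], strand = d$strand[i],
               start = as.integer(vapply(parts, `[`, "", 1L)),
               end = as.integer(vapply(parts, `[`, "", 2L)),
               exon_rank = seq_along(parts), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$exon_rank), ]
  rownames(out) <- NULL
  out
}
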