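#' Simulation parameter profiles
#'
#' Profiles combine a per-base mutation rate (`mL` = 0, `mH` = 0.01), a read
#' length (`len050` = 50 bp, `len100` = 100 bp) and a per-base sequencing
#' error rate (`eL` = 0.0001, `eH` = 0.01), named on the
#' `m{L,H}.len{050,100}.e{L,H}` grammar.
#'
#' @param name profile name, e.g. `"mH.len100.eL"`.
#' @return list of class `sim_profile` with `name`, `mutation_rate`,
#'   `read_length`, `error_rate`.
#' @export
sim_profile <- function(name) {
  m <- regmatches(name, regexec("^m([LH])\\.len(050|100)\\.e([LH])$", name))[[1]]
  if (length(m) == 0) stop("profile name must match m{L,H}.len{050,100}.e{L,H}: ", name)
  structure(list(name = name,
                 mutation_rate = if (m[2] == "H") 0.01 else 0,
                 read_length = as.integer(m[3]),
                 error_rate = if (m[4] == "H") 0.01 else 0.0001),
            class = "sim_profile")
}

#' Mutate a genome, recording ground-truth variants
#'
#' Each base is independently mutated with probability `mutation_rate`; a
#' mutation is an SNV with probability `snv_fraction` (default 0.9, i.e. a
#' 9:1 SNV:indel split) and otherwise an indel (insertion or deletion with
#' equal probability, geometric length). Truth records are in reference
#' coordinates. Reads are later drawn from the mutated genome; the returned
#' coordinate maps convert their positions back to reference coordinates.
#'
#' @param g an `xeno_genome` (a reference).
#' @param mutation_rate per-base mutation probability.
#' @param snv_fraction probability a mutation is an SNV rather than an indel.
#' @param indel_length_mean mean indel length (geometric, minimum 1).
#' @param seed integer seed.
#' @return list with `genome` (mutated), `truth` (data frame: `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `vtype` in SNV/INS/DEL) and `maps`
#'   (per-chromosome coordinate maps for [lift_intervals()]).
#' @export
mutate_genome <- function(g, mutation_rate, snv_fraction = 0.9,
                          indel_length_mean = 2, seed = 1L) {
  stopifnot(inherits(g, "xeno_genome"))
  if (mutation_rate < 0 || mutation_rate > 1 || snv_fraction < 0 || snv_fraction > 1)
    stop("rates must be in [0, 1]")
  empty_truth <- data.frame(chrom = character(), pos = integer(),
                            ref_allele = character(), alt_allele = character(),
                            vtype = character(), stringsAsFactors = FALSE)
  with_seed(seed, {
    seqs <- g$seqs
    maps <- setNames(vector("list", length(seqs)), names(seqs))
    truth <- list()
    for (ch in names(seqs)) {
      s <- seqs[[ch]]
      L <- nchar(s)
      hit <- if (mutation_rate > 0) which(runif(L) < mutation_rate) - 1L else integer(0)
      if (length(hit) == 0) {
        maps[[ch]] <- data.frame(ref_at = numeric(0), der_at = numeric(0), off = numeric(0))
        next
      }
      is_snv <- runif(length(hit)) < snv_fraction
      snv_pos <- hit[is_snv]
      snv_alt <- substitute_bases(
        if (length(snv_pos)) substring(s, snv_pos + 1L, snv_pos + 1L)
        else character(0))
      indels <- NULL
      ind_pos <- hit[!is_snv]
      if (length(ind_pos) > 0) {
        type <- sample(c("INS", "DEL"), length(ind_pos), replace = TRUE)
        len <- rgeom(length(ind_pos), 1 / indel_length_mean) + 1L
        alt <- vapply(seq_along(ind_pos), function(i) {
          if (type[i] == "INS") paste(sample(DNA_BASES, len[i], replace = TRUE), collapse = "")
          else ""
        }, "")
        indels <- data.frame(pos = ind_pos, type = type, len = len, alt = alt,
                             stringsAsFactors = FALSE)
      }
      ed <- edit_sequence(s, snv_pos, snv_alt, indels)
      seqs[[ch]] <- ed$seq
      maps[[ch]] <- ed$map
      rows <- data.frame(chrom = ch, pos = ed$snv$pos,
                         ref_allele = ed$snv$ref_allele,
                         alt_allele = ed$snv$alt_allele,
                         vtype = "SNV", stringsAsFactors = FALSE)
      if (!is.null(ed$indels) && nrow(ed$indels) > 0) {
        rows <- rbind(rows, data.frame(
          chrom = ch, pos = ed$indels$pos, ref_allele = ed$indels$ref_allele,
          alt_allele = ed$indels$alt, vtype = ed$indels$type,
          stringsAsFactors = FALSE))
      }
      truth[[ch]] <- rows[order(rows$pos), ]
    }
    truth <- if (length(truth)) do.call(rbind, truth) else empty_truth
    rownames(truth) <- NULL
    list(genome = genome(g$name, seqs), truth = truth, maps = maps)
  })
}

# Encode/parse read-identifier truth records (underscore-joined, in the
# spirit of the DWGSIM naming convention):
#   <origin>_<chrom>_<start>_<strand>_<n_errors>_<serial>
# `start` is the 0-based leftmost position of the source substring on the
# genome named in the id (reference coordinates when a coordinate map was
# supplied at simulation time).
encode_read_id <- function(origin, chrom, start, strand, n_err, serial) {
  sprintf("%s_%s_%d_%s_%d_%d", origin, chrom, start, strand, n_err, serial)
}

#' Parse read-identifier truth records
#'
#' @param ids character vector of read identifiers produced by
#'   [simulate_reads()].
#' @return data frame with `origin`, `chrom`, `start`, `strand`, `n_err`,
#'   `serial`.
#' @export
parse_read_id <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- lengths(parts) != 6L
  if (any(bad)) stop("unparseable read id(s): ", ids[which(bad)[1]])
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  data.frame(read_id = ids, origin = m[, 1], chrom = m[, 2],
             start = as.integer(m[, 3]), strand = m[, 4],
             n_err = as.integer(m[, 5]), serial = as.integer(m[, 6]),
             stringsAsFactors = FALSE)
}

#' Simulate fixed-length reads with ground truth
#'
#' Draws `round(depth * total_region_length / read_length)` single-end reads
#' with uniform start positions within the regions, uniform strand, and
#' independent per-base errors (each erroneous base becomes a different,
#' uniformly chosen base). All bases carry the flat Phred quality
#' `min(40, round(-10*log10(error_rate)))` (40 when `error_rate` is 0).
#'
#' @param g an `xeno_genome` to read from (typically a mutated sample genome).
#' @param regions `"whole"` or a `chrom`/`start`/`end` data frame in `g`'s
#'   coordinates. Regions shorter than `read_length` are skipped with a
#'   warning.
#' @param read_length read length in bp.
#' @param error_rate per-base sequencing error probability.
#' @param depth target fold-coverage of the regions.
#' @param seed integer seed.
#' @param coord_map optional per-chromosome maps (from [mutate_genome()]);
#'   when supplied, truth start positions are converted from `g`'s
#'   coordinates back to reference coordinates.
#' @param origin origin label stored in read ids (defaults to `g$name`).
#' @return a `read_set` data frame: `read_id`, `sequence`, `quality` (flat
#'   Phred score), plus the truth fields.
#' @export
simulate_reads <- function(g, regions = "whole", read_length, error_rate,
                           depth, seed = 1L, coord_map = NULL,
                           origin = g$name) {
  stopifnot(inherits(g, "xeno_genome"), read_length > 0, depth > 0,
            error_rate >= 0, error_rate <= 1)
  lens <- genome_lengths(g)
  if (identical(regions, "whole")) {
    regions <- data.frame(chrom = names(lens), start = 0L, end = as.integer(lens),
                          stringsAsFactors = FALSE)
  }
  if (grepl("_", origin)) stop("origin label may not contain '_'")
  short <- regions$end - regions$start < read_length
  if (any(short)) {
    warning(sum(short), " region(s) shorter than the read length were skipped")
    regions <- regions[!short, , drop = FALSE]
  }
  if (nrow(regions) == 0) stop("no region long enough for the read length")
  # Starts are uniform within each region (reads may overhang the region
  # end) but a full read must fit on the chromosome.
  max_start <- pmin(regions$end - 1L, as.integer(lens[regions$chrom]) - read_length)
  n_starts <- max_start - regions$start + 1L
  bad <- n_starts <= 0
  if (any(bad)) {
    regions <- regions[!bad, , drop = FALSE]
    n_starts <- n_starts[!bad]
  }
  if (nrow(regions) == 0) stop("no region long enough for the read length")
  total_len <- interval_total_length(regions)
  n_reads <- round(depth * total_len / read_length)
  if (n_reads == 0) {
    return(empty_read_set())
  }
  with_seed(seed, {
    ridx <- sample.int(nrow(regions), n_reads, replace = TRUE, prob = n_starts)
    start <- regions$start[ridx] +
      floor(runif(n_reads) * n_starts[ridx])
    chrom <- regions$chrom[ridx]
    strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
    seqs <- substring(g$seqs[chrom], start + 1L, start + read_length)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    inj <- cpp_inject_errors(seqs, error_rate)
    qual <- if (error_rate <= 0) 40L else as.integer(min(40, round(-10 * log10(error_rate))))
    ref_start <- start
    if (!is.null(coord_map)) {
      for (ch in unique(chrom)) {
        sel <- chrom == ch
        ref_start[sel] <- map_positions(start[sel], coord_map[[ch]], "der2ref")
      }
    }
    out <- data.frame(
      read_id = encode_read_id(origin, chrom, as.integer(ref_start), strand,
                               inj$n_err, seq_len(n_reads)),
      sequence = inj$seq, quality = qual, origin = origin, chrom = chrom,
      start = as.integer(ref_start), strand = strand, n_err = inj$n_err,
      stringsAsFactors = FALSE)
    class(out) <- c("read_set", class(out))
    out
  })
}

empty_read_set <- function() {
  out <- data.frame(read_id = character(), sequence = character(),
                    quality = integer(), origin = character(),
                    chrom = character(), start = integer(),
                    strand = character(), n_err = integer(),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", class(out))
  out
}

#' Mix host and graft read pools at a fixed ratio
#'
#' Draws exactly `round(total_reads * h / (h + g))` reads from the host pool
#' and the complement from the graft pool (both without replacement) and
#' shuffles their order.
#'
#' @param host_reads,graft_reads `read_set` data frames.
#' @param host_to_graft_ratio integer pair `c(h, g)`, e.g. `c(9, 1)`.
#' @param total_reads total number of reads in the mixture.
#' @param seed integer seed.
#' @return a shuffled `read_set`.
#' @export
mix_reads <- function(host_reads, graft_reads, host_to_graft_ratio = c(9, 1),
                      total_reads, seed = 1L) {
  r <- host_to_graft_ratio
  stopifnot(length(r) == 2, all(r >= 0), sum(r) > 0, total_reads >= 0)
  n_host <- round(total_reads * r[1] / sum(r))
  n_graft <- total_reads - n_host
  if (n_host > nrow(host_reads))
    stop("host pool too small: need ", n_host, ", have ", nrow(host_reads))
  if (n_graft > nrow(graft_reads))
    stop("graft pool too small: need ", n_graft, ", have ", nrow(graft_reads))
  with_seed(seed, {
    h <- host_reads[sample.int(nrow(host_reads), n_host), , drop = FALSE]
    g <- graft_reads[sample.int(nrow(graft_reads), n_graft), , drop = FALSE]
    out <- rbind(h, g)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Effective fold-coverage contributed by one origin
#'
#' The fold-coverage perceived for reads of one origin after mixing: e.g. a
#' 60x mixture at 9:1 host:graft carries 60 * 0.9 = 54x of host data.
#'
#' @param total_depth total fold-coverage of the mixture.
#' @param host_fraction fraction of reads from the origin of interest.
#' @return fold-coverage, `total_depth * host_fraction`.
#' @export
effective_depth <- function(total_depth, host_fraction) {
  stopifnot(host_fraction >= 0, host_fraction <= 1)
  total_depth * host_fraction
}

#' Write / read FASTQ (Sanger, Phred+33)
#'
#' @param reads a `read_set`.
#' @param path FASTQ path.
#' @return `write_fastq()` returns `path` invisibly; `read_fastq()` a
#'   `read_set` (truth fields re-parsed from the identifiers).
#' @export
write_fastq <- function(reads, path) {
  qchar <- vapply(seq_len(nrow(reads)), function(i) {
    strrep(intToUtf8(reads$quality[i] + 33L), nchar(reads$sequence[i]))
  }, "")
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence, "+", qchar))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", lines[seq(1, length(lines), by = 4)])
  seqs <- lines[seq(2, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  q <- vapply(quals, function(x) utf8ToInt(substr(x, 1, 1)) - 33L, 1L,
              USE.NAMES = FALSE)
  truth <- parse_read_id(ids)
  out <- data.frame(read_id = ids, sequence = seqs, quality = q,
                    origin = truth$origin, chrom = truth$chrom,
                    start = truth$start, strand = truth$strand,
                    n_err = truth$n_err, stringsAsFactors = FALSE)
  class(out) <- c("read_set", class(out))
  out
}

#' Export ground-truth variants as a tab-separated table
#'
#' @param truth the truth data frame from [mutate_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
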