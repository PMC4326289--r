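# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so seeded operations compose.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over `A`/`C`/`G`/`T`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  cpp_revcomp(as.character(x))
}

# Draw n random bases with P(G) + P(C) = gc_fraction, split evenly within
# the GC and AT pairs.
random_bases <- function(n, gc_fraction = 0.5) {
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
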