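#' @keywords internal
"_PACKAGE"

# Deterministic sub-stream seeds. Streams are partitioned per (genome, sample,
# purpose) so adding a genome or sample never perturbs the draws of the others.
# Kept below 2^31 - 1 so the result is a valid R integer seed.
derive_seed <- function(seed, ...) {
  keys <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    kn <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.numeric(k)
    h <- (h * 48271 + kn * 16807 + 11) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a temporary RNG state seeded from (seed, keys...),
# restoring the caller's stream afterwards.
with_stream <- function(seed, keys, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(do.call(derive_seed, c(list(seed), as.list(keys))))
  expr
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of a nucleotide string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' `U` is treated as `T`.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
rev_comp <- function(x) {
  x <- chartr("uU", "tT", x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
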