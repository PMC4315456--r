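# Shared internal helpers.

#' Taxonomic ranks used throughout the package
#'
#' `TAXONOMIC_RANKS` lists the seven ranks of a Greengenes-style lineage in
#' order; `CLASSIFICATION_RANKS` are the five ranks for which models are
#' trained (phylum through genus).
#'
#' @export
TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                     "genus", "species")

#' @rdname TAXONOMIC_RANKS
#' @export
CLASSIFICATION_RANKS <- c("phylum", "class", "order", "family", "genus")

RANK_PREFIXES <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                   family = "f", genus = "g", species = "s")

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed runs `expr` in the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so we can save state
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream index, kept within
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + stream * 104729) %% 2147483647L)
}

# round() uses banker's rounding; the mtry search specifies round-half-up.
round_half_up <- function(x) floor(x + 0.5)

#' Reverse complement of DNA strings
#'
#' IUPAC ambiguity codes are complemented correctly (e.g. R -> Y).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uppercase and map RNA U to T; validates nothing else.
normalize_sequence <- function(x) {
  chartr("U", "T", toupper(x))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
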