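# Normalized k-mer frequency features: the forest's input representation.

#' Size of the k-mer feature space
#'
#' The number of distinct DNA words of length k over {A,C,G,T}, i.e. 4^k —
#' 256 variables for the default k = 4.
#'
#' @param k word length, a positive integer.
#' @return 4^k as an integer (double for k > 15).
#' @export
feature_space_size <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != as.integer(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  4^k
}

#' All k-mers over {A,C,G,T} in lexicographic order
#'
#' @param k word length.
#' @return character vector of length 4^k.
#' @export
kmer_alphabet <- function(k) {
  names(Biostrings::oligonucleotideFrequency(Biostrings::DNAString(""),
                                             width = k))
}

#' Normalized k-mer frequency vector of one sequence
#'
#' Counts overlapping windows (step 1). Windows containing any non-ACGT
#' symbol are excluded from both the numerator and the denominator, so the
#' frequency of a k-mer is its count divided by the number of valid windows.
#' K-mers are plain (non-canonical): a sequence and its reverse complement
#' generally featurize differently, so reads must be in primer-defined
#' orientation.
#'
#' @param sequence a DNA string (IUPAC codes tolerated, skipped in windows).
#' @param k word length in 2..8.
#' @return a named numeric vector of length 4^k summing to 1 (all zeros if
#'   the sequence has no valid window), with attributes `k` and
#'   `valid_kmer_count`.
#' @export
kmer_frequencies <- function(sequence, k) {
  m <- featurize_batch(sequence, k)
  v <- m[1, ]
  attr(v, "k") <- k
  attr(v, "valid_kmer_count") <- attr(m, "valid_kmer_counts")[1]
  v
}

#' K-mer frequency matrix for a batch of sequences
#'
#' Rows align with the input order; columns are the k-mer alphabet in
#' lexicographic order, optionally restricted to a subset. Restriction
#' happens after normalization over all valid windows — frequencies are not
#' renormalized to the subset, so subset rows may sum to less than 1.
#'
#' @param sequences character vector of DNA strings.
#' @param k word length in 2..8.
#' @param variable_subset `"all"` or a character vector of k-mers to keep
#'   (reported in lexicographic order).
#' @return numeric matrix `length(sequences)` x `|subset|` with attribute
#'   `valid_kmer_counts` (integer per row).
#' @export
featurize_batch <- function(sequences, k, variable_subset = "all") {
  if (k < 2 || k > 8) stop("k must be in 2..8", call. = FALSE)
  set <- Biostrings::DNAStringSet(toupper(sequences))
  counts <- Biostrings::oligonucleotideFrequency(set, width = k, step = 1L)
  valid <- as.integer(rowSums(counts))
  freqs <- counts
  nz <- valid > 0
  freqs[nz, ] <- counts[nz, , drop = FALSE] / valid[nz]
  freqs[!nz, ] <- 0
  if (!identical(variable_subset, "all")) {
    bad <- setdiff(variable_subset, colnames(freqs))
    if (length(bad)) {
      stop("not ", k, "-mers over ACGT: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    freqs <- freqs[, sort(unique(variable_subset)), drop = FALSE]
  }
  rownames(freqs) <- names(sequences)
  attr(freqs, "valid_kmer_counts") <- valid
  freqs
}

#' Write a feature matrix as TSV (k-mer column headers)
#'
#' @param features matrix from [featurize_batch()].
#' @param path output path.
#' @param ids row ids written as the first column.
#' @return invisibly, `path`.
#' @export
write_feature_matrix <- function(features, path,
                                 ids = rownames(features)) {
  df <- data.frame(id = ids %||% seq_len(nrow(features)), features,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
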