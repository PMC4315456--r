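# Independent oracles and shared fixtures for the test suite. The oracles
# deliberately re-implement operations by the most literal route possible
# (dictionary counts, sliding windows, direct formulas) so they share no
# code with the package internals they check.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# Brute-force primer scan: score every window by IUPAC-aware Hamming
# distance (letters match when their expansion sets intersect), return the
# leftmost window among those with the fewest mismatches <= max_mm.
oracle_match_primer <- function(sequence, primer, max_mm) {
  sc <- strsplit(sequence, "")[[1]]
  pc <- strsplit(primer, "")[[1]]
  n <- length(sc); m <- length(pc)
  if (n == 0 || m > n) return(NULL)
  best_pos <- NA_integer_; best_mm <- Inf
  for (start in 0:(n - m)) {
    mm <- 0L
    for (j in seq_len(m)) {
      a <- IUPAC_SETS[[sc[start + j]]]
      b <- IUPAC_SETS[[pc[j]]]
      if (length(intersect(a, b)) == 0) mm <- mm + 1L
    }
    if (mm < best_mm) { best_mm <- mm; best_pos <- start }
  }
  if (best_mm > max_mm) return(NULL)
  list(position = best_pos, mismatches = as.integer(best_mm))
}

# Dictionary-count k-mer oracle: enumerate windows, drop any containing a
# non-ACGT letter, count, divide by valid window count.
oracle_kmer_frequencies <- function(sequence, k) {
  kmers <- kmer_alphabet(k)
  counts <- stats::setNames(rep(0, length(kmers)), kmers)
  n <- nchar(sequence)
  valid <- 0L
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      w <- substr(sequence, i, i + k - 1)
      if (grepl("^[ACGT]+$", w)) {
        counts[w] <- counts[w] + 1
        valid <- valid + 1L
      }
    }
  }
  if (valid > 0) counts <- counts / valid
  list(freqs = counts, valid = valid)
}

# Direct transcription of the seven metric formulas.
oracle_metrics <- function(tp, fp, fn, tn) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  acc <- if (tp + fp + fn + tn > 0) (tp + tn) / (tp + fp + fn + tn) else NA_real_
  g <- sqrt(sens * spec)
  f <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else NA_real_
  c(sensitivity = sens, specificity = spec, precision = prec,
    accuracy = acc, g_mean = g, f_measure = f, mcc = mcc)
}

# All-pairs greedy clustering oracle for equal-length sequences, where
# global identity is unambiguously the Hamming identity.
oracle_greedy_clusters <- function(sequences, threshold) {
  ident <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  reps <- character(0)
  assignment <- integer(length(sequences))
  for (i in seq_along(sequences)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (ident(sequences[i], reps[ci]) >= threshold) {
        assignment[i] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, sequences[i])
      assignment[i] <- length(reps)
    }
  }
  assignment
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Shared default fixture and a classifier trained on reads from it; built
# once per test run.
.shared <- new.env(parent = emptyenv())

shared_fixture <- function() {
  if (is.null(.shared$fixture)) {
    .shared$fixture <- generate_reference(fixture_design())
  }
  .shared$fixture
}

shared_classifier <- function() {
  if (is.null(.shared$classifier)) {
    fx <- shared_fixture()
    rd <- generate_reads(fx, "V3")
    .shared$reads <- rd
    .shared$classifier <- train_classifier(
      rd$reads, rd$truth[, TAXONOMIC_RANKS], region = "V3",
      ntree = 100, seed = 5)
  }
  .shared$classifier
}

shared_reads <- function() {
  shared_classifier()
  .shared$reads
}
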