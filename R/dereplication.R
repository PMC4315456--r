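# Redundancy removal before training: exact and greedy identity clustering.

#' Pairwise global identity between two sequences
#'
#' Identity is the number of matching columns in an end-gap-free global
#' alignment divided by the length of the longer sequence. Equal-length
#' pairs are scored by Hamming identity directly (at thresholds near 1
#' almost all merges are substitution-only). Pairs whose length difference
#' alone puts them below `shortcut_threshold` return 0 without aligning.
#'
#' @param a,b DNA strings.
#' @param shortcut_threshold if not `NULL`, skip alignment when the length
#'   difference already forces identity below this value.
#' @return identity in \[0,1\].
#' @export
seq_identity <- function(a, b, shortcut_threshold = NULL) {
  la <- nchar(a); lb <- nchar(b)
  longer <- max(la, lb)
  if (longer == 0L) return(1)
  if (!is.null(shortcut_threshold) &&
      abs(la - lb) > (1 - shortcut_threshold) * longer) {
    return(0)
  }
  if (a == b) return(1)
  if (la == lb) {
    matches <- sum(utf8ToInt(a) == utf8ToInt(b))
    return(matches / longer)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE))
  Biostrings::nmatch(aln) / longer
}

new_cluster_set <- function(clusters, threshold) {
  structure(clusters, class = "cluster_set", threshold = threshold)
}

#' Dereplicate sequences at identity threshold 1 (exact duplicates)
#'
#' Sequences identical as strings share one cluster; the representative is
#' the first-seen member and clusters are listed in order of first
#' appearance.
#'
#' @param sequences character vector of sequences.
#' @param ids sequence ids (defaults to names of `sequences`, else indices).
#' @return a `cluster_set`: a list of clusters, each a list with
#'   `representative_id`, `member_ids`, `identities`, `threshold = 1`.
#' @export
dereplicate_exact <- function(sequences, ids = NULL) {
  stopifnot(length(sequences) > 0)
  ids <- ids %||% names(sequences) %||% as.character(seq_along(sequences))
  fac <- factor(sequences, levels = unique(sequences))
  groups <- split(ids, fac)
  clusters <- lapply(groups, function(members) {
    list(representative_id = members[1], member_ids = members,
         identities = rep(1, length(members)), threshold = 1)
  })
  names(clusters) <- NULL
  new_cluster_set(clusters, threshold = 1)
}

#' Greedy identity clustering below threshold 1 (CD-HIT convention)
#'
#' Sequences are processed longest-first (ties by input order); each joins
#' the first existing cluster whose representative it matches at or above
#' the threshold, else founds a new cluster. Because of the ordering, the
#' representative of every cluster is its longest member. A threshold of 1
#' is routed to [dereplicate_exact()].
#'
#' @param sequences character vector of sequences.
#' @param threshold global identity threshold in (0, 1\].
#' @param ids sequence ids (defaults to names, else indices).
#' @return a `cluster_set` (see [dereplicate_exact()]).
#' @export
dereplicate_greedy <- function(sequences, threshold, ids = NULL) {
  stopifnot(length(sequences) > 0, threshold > 0, threshold <= 1)
  if (threshold == 1) return(dereplicate_exact(sequences, ids))
  ids <- ids %||% names(sequences) %||% as.character(seq_along(sequences))
  ord <- order(-nchar(sequences))  # stable: ties keep input order
  reps <- character(0)
  rep_ids <- character(0)
  members <- list()
  identities <- list()
  for (i in ord) {
    s <- sequences[i]
    placed <- FALSE
    for (ci in seq_along(reps)) {
      ident <- seq_identity(s, reps[ci], shortcut_threshold = threshold)
      if (ident >= threshold) {
        members[[ci]] <- c(members[[ci]], ids[i])
        identities[[ci]] <- c(identities[[ci]], ident)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, s)
      rep_ids <- c(rep_ids, ids[i])
      members[[length(members) + 1L]] <- ids[i]
      identities[[length(identities) + 1L]] <- 1
    }
  }
  clusters <- lapply(seq_along(reps), function(ci) {
    list(representative_id = rep_ids[ci], member_ids = members[[ci]],
         identities = identities[[ci]], threshold = threshold)
  })
  new_cluster_set(clusters, threshold = threshold)
}

#' Flatten a cluster set to a table
#'
#' @param clusters a `cluster_set`.
#' @return a data.frame with columns `representative_id`, `member_id`,
#'   `identity`.
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(representative_id = cl$representative_id,
               member_id = cl$member_ids, identity = cl$identities,
               stringsAsFactors = FALSE)
  }))
}

#' Representative ids of a cluster set
#'
#' @param clusters a `cluster_set`.
#' @return character vector of representative ids, in cluster order.
#' @export
cluster_representatives <- function(clusters) {
  vapply(clusters, function(cl) cl$representative_id, character(1))
}
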