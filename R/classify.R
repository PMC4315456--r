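# Train the per-rank model set and assign taxonomy to amplicon reads.

CLASSIFIER_FORMAT_VERSION <- "1.0"

#' Train a per-rank classifier for one hypervariable region
#'
#' Featurizes the training sequences once and fits one forest per
#' taxonomic rank (phylum through genus by default). Ranks are trained
#' independently on their own label groups; sequences unlabelled at a rank
#' are excluded from that rank's forest. Also retains the table of distinct
#' training lineages, which the optional hierarchically-consistent
#' classification mode uses.
#'
#' @param sequences character vector of region sequences (primer-trimmed),
#'   named by sequence id.
#' @param lineages data.frame of rank columns aligned with `sequences`
#'   (as produced by [read_reference()]; only the rank columns are used).
#' @param region region label the sequences came from.
#' @param k k-mer size (default 4).
#' @param ntree trees per forest (default 1000).
#' @param mtry variables tried per split; `NULL` uses [default_mtry()],
#'   `"tune"` runs [tune_mtry()] per rank.
#' @param variable_subset `"all"` or a vector of k-mers.
#' @param ranks ranks to train (default [CLASSIFICATION_RANKS]).
#' @param seed integer seed; per-rank forests draw derived seeds.
#' @param rare_label_action passed to [train_rank_model()].
#' @return an `hvr_classifier`: list with `region`, `k`, `variable_subset`,
#'   `kingdom`, `taxonomy` (distinct training lineages), `ranks` (named
#'   list of `rank_model`s) and `format_version`.
#' @export
train_classifier <- function(sequences, lineages, region, k = 4,
                             ntree = 1000, mtry = NULL,
                             variable_subset = "all",
                             ranks = CLASSIFICATION_RANKS, seed = 1L,
                             rare_label_action = "drop") {
  stopifnot(length(sequences) == nrow(lineages))
  features <- featurize_batch(sequences, k, variable_subset)
  bundles <- list()
  for (ri in seq_along(ranks)) {
    rank <- ranks[ri]
    labels <- lineages[[rank]]
    labelled <- !is.na(labels) & labels != ""
    if (sum(labelled) == 0) next
    rank_seed <- derive_seed(seed, ri)
    rank_mtry <- mtry
    if (identical(mtry, "tune")) {
      trace <- tune_mtry(features[labelled, , drop = FALSE],
                         labels[labelled], ntree = min(ntree, 200),
                         seed = rank_seed)
      rank_mtry <- attr(trace, "chosen_mtry")
    }
    bundles[[rank]] <- train_rank_model(
      features[labelled, , drop = FALSE], labels[labelled], rank = rank,
      k = k, ntree = ntree, mtry = rank_mtry, seed = rank_seed,
      rare_label_action = rare_label_action)
  }
  kingdoms <- unique(lineages$kingdom[lineages$kingdom != ""])
  taxonomy <- unique(lineages[, intersect(TAXONOMIC_RANKS, names(lineages)),
                              drop = FALSE])
  structure(list(region = region, k = k,
                 variable_subset = variable_subset,
                 kingdom = if (length(kingdoms) == 1) kingdoms else "",
                 taxonomy = taxonomy,
                 ranks = bundles,
                 format_version = CLASSIFIER_FORMAT_VERSION),
            class = "hvr_classifier")
}

#' @export
print.hvr_classifier <- function(x, ...) {
  cat("hvr_classifier for region", x$region, "(k =", x$k, ")\n")
  for (rank in names(x$ranks)) {
    b <- x$ranks[[rank]]
    cat(sprintf("  %-7s %4d taxa  mtry %3d  ntree %4d  OOB error %.4f\n",
                rank, length(b$label_space), b$mtry, b$ntree, b$oob_error))
  }
  invisible(x)
}

#' Save / load a trained classifier
#'
#' The classifier is written to a versioned directory: a JSON manifest with
#' the region, k-mer size, per-rank tuning metadata and label spaces, plus
#' one serialized forest per rank. Loading refuses manifests whose format
#' version does not match the package's.
#'
#' @param classifier an `hvr_classifier`.
#' @param dir target directory (created if missing).
#' @return `save_classifier` invisibly returns `dir`; `load_classifier`
#'   returns the `hvr_classifier`.
#' @export
save_classifier <- function(classifier, dir) {
  stopifnot(inherits(classifier, "hvr_classifier"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format_version = classifier$format_version,
    region = classifier$region,
    k = classifier$k,
    variable_subset = classifier$variable_subset,
    kingdom = classifier$kingdom,
    ranks = lapply(classifier$ranks, function(b) {
      list(rank = b$rank, mtry = b$mtry, ntree = b$ntree,
           oob_error = b$oob_error, label_space = b$label_space,
           seed = b$training_manifest$seed,
           trained_at = b$training_manifest$trained_at)
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(classifier$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (rank in names(classifier$ranks)) {
    rd <- file.path(dir, rank)
    dir.create(rd, showWarnings = FALSE)
    saveRDS(classifier$ranks[[rank]], file.path(rd, "model.rds"))
  }
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no classifier manifest at ", manifest_path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(manifest$format_version, CLASSIFIER_FORMAT_VERSION)) {
    stop("classifier format version ", manifest$format_version,
         " does not match supported version ", CLASSIFIER_FORMAT_VERSION,
         call. = FALSE)
  }
  ranks <- list()
  for (rank in names(manifest$ranks)) {
    ranks[[rank]] <- readRDS(file.path(dir, rank, "model.rds"))
  }
  taxonomy <- utils::read.table(file.path(dir, "taxonomy.tsv"), sep = "\t",
                                header = TRUE, colClasses = "character",
                                quote = "", comment.char = "")
  structure(list(region = manifest$region, k = manifest$k,
                 variable_subset = manifest$variable_subset,
                 kingdom = manifest$kingdom %||% "",
                 taxonomy = taxonomy,
                 ranks = ranks,
                 format_version = manifest$format_version),
            class = "hvr_classifier")
}

# Vote matrix (rows = reads, cols = label space) for one rank's forest.
rank_votes <- function(bundle, features) {
  v <- stats::predict(bundle$model, features, type = "vote",
                      norm.votes = TRUE)
  matrix(v, nrow = nrow(features), dimnames = dimnames(v))
}

#' Assign taxonomy to amplicon reads
#'
#' Each read is featurized with the classifier's k-mer size and variable
#' subset; each rank's forest votes independently and the majority taxon is
#' reported with its vote fraction. Taxa whose vote fraction falls below
#' `confidence_threshold` are reported as `"Unclassified"` at that rank and
#' every rank below it. Reads too short to contain a single valid k-mer
#' window are Unclassified at all ranks with reason `"too_short"`.
#'
#' Ranks are predicted independently and may be hierarchically
#' inconsistent; `consistent = TRUE` instead walks down from phylum,
#' restricting each rank's candidates to children (in the training
#' taxonomy) of the taxon chosen at the rank above.
#'
#' @param reads named character vector of read sequences (FASTA/FASTQ via
#'   [read_sequences()]), in primer-defined orientation (see
#'   [orient_reads()]).
#' @param classifier an `hvr_classifier`.
#' @param region region the reads come from; must match the classifier's.
#' @param confidence_threshold minimum vote fraction to report a taxon
#'   (default 0: always report the top vote).
#' @param consistent enforce hierarchical consistency (default FALSE).
#' @return a data.frame with one row per read: `query_id`, `region`,
#'   `orientation`, a `<rank>` and `<rank>_vote` column per rank, the
#'   assembled rank-tagged `lineage` string, and `reason`.
#' @export
classify_reads <- function(reads, classifier, region = classifier$region,
                           confidence_threshold = 0, consistent = FALSE) {
  stopifnot(inherits(classifier, "hvr_classifier"), length(reads) > 0)
  if (!identical(region, classifier$region)) {
    stop("no model bundle for region '", region, "' (classifier was ",
         "trained for '", classifier$region, "')", call. = FALSE)
  }
  ids <- names(reads) %||% as.character(seq_along(reads))
  ranks <- names(classifier$ranks)
  features <- featurize_batch(reads, classifier$k,
                              classifier$variable_subset)
  usable <- attr(features, "valid_kmer_counts") > 0
  n <- length(reads)
  out <- data.frame(query_id = ids, region = region,
                    orientation = "forward", stringsAsFactors = FALSE)
  votes <- list()
  if (any(usable)) {
    for (rank in ranks) {
      votes[[rank]] <- rank_votes(classifier$ranks[[rank]],
                                  features[usable, , drop = FALSE])
    }
  }
  taxon <- matrix("Unclassified", nrow = n, ncol = length(ranks),
                  dimnames = list(NULL, ranks))
  vote_frac <- matrix(NA_real_, nrow = n, ncol = length(ranks),
                      dimnames = list(NULL, ranks))
  which_usable <- which(usable)
  for (j in seq_along(which_usable)) {
    i <- which_usable[j]
    parent <- NULL
    below_threshold <- FALSE
    for (ri in seq_along(ranks)) {
      rank <- ranks[ri]
      v <- votes[[rank]][j, ]
      if (consistent && !is.null(parent) && ri > 1) {
        kids <- unique(classifier$taxonomy[[rank]][
          classifier$taxonomy[[ranks[ri - 1]]] == parent])
        kids <- intersect(kids, names(v))
        if (length(kids)) v <- v[kids]
      }
      top <- which.max(v)
      vote_frac[i, ri] <- unname(v[top])
      if (below_threshold || v[top] < confidence_threshold) {
        below_threshold <- TRUE
        taxon[i, ri] <- "Unclassified"
        parent <- NULL
      } else {
        taxon[i, ri] <- names(v)[top]
        parent <- names(v)[top]
      }
    }
  }
  for (ri in seq_along(ranks)) {
    out[[ranks[ri]]] <- taxon[, ri]
    out[[paste0(ranks[ri], "_vote")]] <- vote_frac[, ri]
  }
  out$lineage <- assemble_lineage_strings(out, ranks, classifier$kingdom)
  out$reason <- ifelse(usable, NA_character_, "too_short")
  attr(out, "votes") <- votes
  out
}

# Rank-tagged lineage string; Unclassified ranks render as empty tags.
assemble_lineage_strings <- function(results, ranks, kingdom = "") {
  all_ranks <- c("kingdom", ranks)
  vapply(seq_len(nrow(results)), function(i) {
    parts <- character(length(all_ranks))
    parts[1] <- paste0("k__", kingdom)
    for (ri in seq_along(ranks)) {
      taxon <- results[[ranks[ri]]][i]
      if (identical(taxon, "Unclassified")) taxon <- ""
      parts[ri + 1] <- paste0(RANK_PREFIXES[[ranks[ri]]], "__", taxon)
    }
    paste(parts, collapse = ";")
  }, character(1))
}

#' Orient reads against a classifier
#'
#' Classifies each read and its reverse complement at the first (phylum)
#' rank and keeps the orientation with the higher top vote fraction; ties
#' keep the forward orientation. Use when query reads are of mixed or
#' unknown strandedness.
#'
#' @param reads named character vector of read sequences.
#' @param classifier an `hvr_classifier`.
#' @return a list: `reads` (oriented sequences, same names and order) and
#'   `orientation` (`"forward"`/`"reverse"` per read).
#' @export
orient_reads <- function(reads, classifier) {
  stopifnot(length(reads) > 0)
  first_rank <- names(classifier$ranks)[1]
  bundle <- classifier$ranks[[first_rank]]
  top_vote <- function(seqs) {
    f <- featurize_batch(seqs, classifier$k, classifier$variable_subset)
    ok <- attr(f, "valid_kmer_counts") > 0
    out <- rep(-Inf, length(seqs))
    if (any(ok)) {
      v <- rank_votes(bundle, f[ok, , drop = FALSE])
      out[ok] <- apply(v, 1, max)
    }
    out
  }
  fwd <- top_vote(reads)
  rev <- top_vote(revcomp(reads))
  use_rev <- rev > fwd  # ties keep forward
  oriented <- ifelse(use_rev, revcomp(reads), reads)
  names(oriented) <- names(reads)
  list(reads = oriented,
       orientation = ifelse(use_rev, "reverse", "forward"))
}

#' Write classifications in QIIME taxonomy-assignment format
#'
#' Three tab-separated fields per read, in input order: query id,
#' semicolon-delimited rank-tagged lineage, and confidence (the minimum
#' vote fraction over the assigned ranks; 0 when nothing was assigned).
#'
#' @param results data.frame from [classify_reads()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_qiime_assignments <- function(results, path) {
  stopifnot(nrow(results) > 0)
  ranks <- intersect(CLASSIFICATION_RANKS, names(results))
  conf <- vapply(seq_len(nrow(results)), function(i) {
    assigned <- vapply(ranks, function(r) {
      !identical(results[[r]][i], "Unclassified")
    }, logical(1))
    if (!any(assigned)) return(0)
    min(vapply(ranks[assigned], function(r) results[[paste0(r, "_vote")]][i],
               numeric(1)))
  }, numeric(1))
  lines <- paste(results$query_id, results$lineage,
                 formatC(conf, digits = 4, format = "f"), sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a QIIME taxonomy-assignment file
#'
#' @param path path written by [write_qiime_assignments()] (or by QIIME's
#'   assign_taxonomy step).
#' @return a data.frame with `query_id`, `lineage`, `confidence` and one
#'   parsed column per rank.
#' @export
read_qiime_assignments <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", colClasses = "character",
                           col.names = c("query_id", "lineage",
                                         "confidence"))
  lin <- parse_lineage(tab$lineage)
  out <- cbind(data.frame(query_id = tab$query_id, lineage = tab$lineage,
                          confidence = as.numeric(tab$confidence),
                          stringsAsFactors = FALSE),
               lin)
  rownames(out) <- NULL
  out
}

#' Read sequences from FASTA or FASTQ
#'
#' Format is detected from the first character (`>` FASTA, `@` FASTQ);
#' FASTQ qualities are ignored. Ids are the first whitespace-delimited
#' token of each header.
#'
#' @param path input path.
#' @return named character vector of upper-cased sequences (U mapped to T).
#' @export
read_sequences <- function(path) {
  first <- readChar(path, 1L)
  set <- if (identical(first, "@")) {
    Biostrings::readBStringSet(path, format = "fastq")
  } else {
    Biostrings::readBStringSet(path, format = "fasta")
  }
  seqs <- normalize_sequence(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}
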