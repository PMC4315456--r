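# Reference sequence + taxonomy ingest and per-rank grouping.

#' Parse Greengenes-style lineage strings
#'
#' Accepts both rank-tagged strings (`"k__Bacteria; p__Firmicutes; ..."`) and
#' bare semicolon-separated names (`"Bacteria;Firmicutes"`), which are
#' assigned to ranks in kingdom-to-species order. Empty rank tags (`"g__"`)
#' and missing trailing ranks yield empty taxon names. Lineages violating the
#' prefix property (a named rank below an unnamed one) are truncated at the
#' first gap with a warning.
#'
#' @param x character vector of lineage strings.
#' @return a data.frame with one character column per rank in
#'   [TAXONOMIC_RANKS] and one row per input string.
#' @export
parse_lineage <- function(x) {
  out <- matrix("", nrow = length(x), ncol = length(TAXONOMIC_RANKS),
                dimnames = list(NULL, TAXONOMIC_RANKS))
  n_truncated <- 0L
  for (i in seq_along(x)) {
    fields <- trimws(strsplit(x[i], ";", fixed = TRUE)[[1]])
    row <- stats::setNames(character(length(TAXONOMIC_RANKS)), TAXONOMIC_RANKS)
    tagged <- grepl("^[kpcofgs]__", fields)
    if (length(fields) && any(tagged)) {
      for (f in fields) {
        tag <- substr(f, 1, 1)
        rank <- names(RANK_PREFIXES)[match(tag, RANK_PREFIXES)]
        if (grepl("^[kpcofgs]__", f) && !is.na(rank)) {
          row[rank] <- trimws(substr(f, 4, nchar(f)))
        }
      }
    } else {
      nn <- min(length(fields), length(TAXONOMIC_RANKS))
      if (nn > 0) row[seq_len(nn)] <- fields[seq_len(nn)]
    }
    # prefix property: first empty rank truncates everything below it
    empty <- which(row == "")
    if (length(empty)) {
      below <- seq(min(empty), length(row))
      if (any(row[below] != "")) n_truncated <- n_truncated + 1L
      row[below] <- ""
    }
    out[i, ] <- row
  }
  if (n_truncated > 0) {
    warning(sprintf(
      "%d lineage(s) violated the prefix property (named rank below an unnamed one); truncated at the first gap",
      n_truncated))
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Format lineages as Greengenes-style strings
#'
#' @param lineage a data.frame with the columns of [TAXONOMIC_RANKS].
#' @param ranks which ranks to include, in order.
#' @param sep separator between rank fields.
#' @return character vector of rank-tagged lineage strings.
#' @export
format_lineage <- function(lineage, ranks = TAXONOMIC_RANKS, sep = "; ") {
  parts <- vapply(ranks, function(r) {
    paste0(RANK_PREFIXES[[r]], "__", lineage[[r]])
  }, character(nrow(lineage)))
  if (nrow(lineage) == 1L) parts <- matrix(parts, nrow = 1)
  apply(parts, 1, paste, collapse = sep)
}

#' Read a reference collection: FASTA plus taxonomy map
#'
#' Reads reference 16S sequences from a FASTA file and joins them with a
#' two-column (id TAB lineage-string) taxonomy map. Sequences are
#' upper-cased and U is mapped to T on ingest. FASTA entries with no
#' taxonomy line are dropped with a warning that reports their count (also
#' available as the `n_unmapped` attribute of the result).
#'
#' @param fasta_path path to a FASTA file of reference sequences.
#' @param taxonomy_path path to a headerless two-column TSV mapping sequence
#'   id to lineage string.
#' @return a data.frame with columns `id`, `sequence` and one column per
#'   rank in [TAXONOMIC_RANKS]; attribute `n_unmapped` counts FASTA entries
#'   without taxonomy.
#' @export
read_reference <- function(fasta_path, taxonomy_path) {
  seqs <- tryCatch(
    Biostrings::readBStringSet(fasta_path),
    error = function(e) stop("malformed FASTA in '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tax <- utils::read.table(taxonomy_path, sep = "\t", header = FALSE,
                           quote = "", comment.char = "",
                           colClasses = "character",
                           col.names = c("id", "lineage"))
  if (anyDuplicated(tax$id)) {
    stop("duplicate id(s) in taxonomy map", call. = FALSE)
  }
  keep <- ids %in% tax$id
  n_unmapped <- sum(!keep)
  if (n_unmapped > 0) {
    warning(sprintf("%d FASTA entr%s had no taxonomy line and were dropped",
                    n_unmapped, if (n_unmapped == 1) "y" else "ies"))
  }
  sequence <- normalize_sequence(as.character(seqs[keep]))
  id <- ids[keep]
  lin <- parse_lineage(tax$lineage[match(id, tax$id)])
  records <- cbind(data.frame(id = id, sequence = unname(sequence),
                              stringsAsFactors = FALSE),
                   lin)
  rownames(records) <- NULL
  attr(records, "n_unmapped") <- n_unmapped
  records
}

#' Write a reference collection back to FASTA + taxonomy TSV
#'
#' Inverse of [read_reference()]: sequences go to FASTA (one line per
#' sequence) and lineages to a two-column TSV in rank-tagged form.
#'
#' @param records a reference data.frame as returned by [read_reference()].
#' @param fasta_path,taxonomy_path output paths.
#' @return invisibly, `records`.
#' @export
write_reference <- function(records, fasta_path, taxonomy_path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, fasta_path, width = 20000L)
  lines <- paste(records$id, format_lineage(records), sep = "\t")
  writeLines(lines, taxonomy_path)
  invisible(records)
}

#' Group reference records by taxon at one rank
#'
#' Produces one group per distinct non-empty taxon name at the given rank.
#' Records with an empty label at that rank are excluded; their count is
#' recorded in the `n_excluded` attribute.
#'
#' @param records a reference data.frame (needs `id` and the rank column).
#' @param rank one of [CLASSIFICATION_RANKS].
#' @return a named list of character vectors of member ids, one element per
#'   taxon, with attributes `rank` and `n_excluded`.
#' @export
group_by_rank <- function(records, rank) {
  if (!rank %in% CLASSIFICATION_RANKS) {
    stop("unknown rank '", rank, "'; must be one of: ",
         paste(CLASSIFICATION_RANKS, collapse = ", "), call. = FALSE)
  }
  labels <- records[[rank]]
  labelled <- !is.na(labels) & labels != ""
  groups <- split(records$id[labelled], labels[labelled])
  # deterministic order: first appearance in the input
  first_seen <- vapply(groups, function(ids) match(ids[1], records$id), 0L)
  groups <- groups[order(first_seen)]
  attr(groups, "rank") <- rank
  attr(groups, "n_excluded") <- sum(!labelled)
  groups
}
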