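# Fuzzy primer matching and hypervariable-region excision.

#' Find the best fuzzy match of an IUPAC primer in a sequence
#'
#' Slides the primer along the sequence with no indels, scoring IUPAC-aware
#' Hamming distance: two letters match when their IUPAC expansion sets
#' intersect (R matches A or G; N matches anything). Returns the leftmost
#' window among those with the fewest mismatches not exceeding
#' `max_mismatches`, or `NULL` when there is none (including when the
#' sequence is empty or shorter than the primer).
#'
#' @param sequence a DNA string (may contain IUPAC codes).
#' @param primer an IUPAC DNA primer string.
#' @param max_mismatches maximum mismatches tolerated.
#' @return `NULL`, or a list with `position` (0-based start of the match)
#'   and `mismatches`.
#' @export
match_primer <- function(sequence, primer, max_mismatches = 0L) {
  sequence <- toupper(sequence); primer <- toupper(primer)
  if (nchar(sequence) == 0L || nchar(primer) > nchar(sequence)) return(NULL)
  subj <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(primer)
  hits <- Biostrings::matchPattern(pat, subj,
                                   max.mismatch = max_mismatches,
                                   with.indels = FALSE, fixed = FALSE)
  if (length(hits) == 0L) return(NULL)
  starts <- Biostrings::start(hits)
  mm <- Biostrings::neditStartingAt(pat, subj, starting.at = starts,
                                    with.indels = FALSE, fixed = FALSE)
  best <- which(mm == min(mm))[1]  # leftmost among fewest mismatches
  list(position = starts[best] - 1L, mismatches = as.integer(mm[best]))
}

extraction_failure <- function(reason) {
  structure(list(matched = FALSE, reason = reason), class = "hvr_extraction")
}

#' Excise a hypervariable region between a primer pair
#'
#' Matches the forward primer, then the reverse complement of the reverse
#' primer downstream of it, and excises the span between the two primer
#' sites (primer sequences removed). If the forward strand fails and
#' `search_both_strands` is TRUE, the reverse complement of the source is
#' searched and the result is reported in primer-defined (forward)
#' orientation, with coordinates on the oriented sequence.
#'
#' @param sequence source DNA string.
#' @param pair a [primer_pair()].
#' @param id source sequence id carried into the result.
#' @param search_both_strands retry on the reverse complement on failure.
#' @return an `hvr_extraction` list: on success `matched = TRUE`, `source_id`,
#'   `region`, `start`/`end` (0-based half-open, on the oriented source),
#'   `sequence`, `fwd_mismatches`, `rev_mismatches`, `orientation`
#'   (`"forward"` or `"reverse"`); on failure `matched = FALSE` plus a
#'   `reason` code (`"forward_not_found"`, `"reverse_not_found"`,
#'   `"empty_region"`).
#' @export
extract_region <- function(sequence, pair, id = NA_character_,
                           search_both_strands = TRUE) {
  stopifnot(inherits(pair, "primer_pair"))
  one_strand <- function(s) {
    fwd <- match_primer(s, pair$forward, pair$max_mismatches)
    if (is.null(fwd)) return(extraction_failure("forward_not_found"))
    region_from <- fwd$position + nchar(pair$forward)  # 0-based
    downstream <- substr(s, region_from + 1L, nchar(s))
    rev_site <- revcomp(pair$reverse)
    rev <- match_primer(downstream, rev_site, pair$max_mismatches)
    if (is.null(rev)) return(extraction_failure("reverse_not_found"))
    start <- region_from
    end <- region_from + rev$position
    if (end <= start) return(extraction_failure("empty_region"))
    structure(list(matched = TRUE, source_id = id, region = pair$region,
                   start = start, end = end,
                   sequence = substr(s, start + 1L, end),
                   fwd_mismatches = fwd$mismatches,
                   rev_mismatches = rev$mismatches,
                   orientation = "forward"),
              class = "hvr_extraction")
  }
  res <- one_strand(sequence)
  if (!res$matched && search_both_strands) {
    res_rc <- one_strand(revcomp(sequence))
    if (res_rc$matched) {
      res_rc$orientation <- "reverse"
      return(res_rc)
    }
  }
  res
}

#' Extract one region from every record in a reference collection
#'
#' @param records a reference data.frame (columns `id`, `sequence`).
#' @param pair a [primer_pair()].
#' @param search_both_strands passed to [extract_region()].
#' @return a data.frame with one row per record: `id`, `region`, `matched`,
#'   `start`, `end`, `sequence`, `fwd_mismatches`, `rev_mismatches`,
#'   `orientation`, `reason`.
#' @export
extract_regions <- function(records, pair, search_both_strands = TRUE) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    r <- extract_region(records$sequence[i], pair, id = records$id[i],
                        search_both_strands = search_both_strands)
    if (r$matched) {
      data.frame(id = records$id[i], region = pair$region, matched = TRUE,
                 start = r$start, end = r$end, sequence = r$sequence,
                 fwd_mismatches = r$fwd_mismatches,
                 rev_mismatches = r$rev_mismatches,
                 orientation = r$orientation, reason = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = records$id[i], region = pair$region, matched = FALSE,
                 start = NA_integer_, end = NA_integer_,
                 sequence = NA_character_, fwd_mismatches = NA_integer_,
                 rev_mismatches = NA_integer_, orientation = NA_character_,
                 reason = r$reason, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Fraction of a reference covered by a primer pair
#'
#' A primer pair is usable for model training only when it recovers the
#' region from a majority of the reference; pairs with coverage at or below
#' 0.5 are flagged rejected (this is what excludes V1/V9-style pairs).
#'
#' @param records reference data.frame.
#' @param pair a [primer_pair()].
#' @param search_both_strands passed to [extract_region()].
#' @return a list: `region`, `coverage` in \[0,1\], `n`, `n_matched`,
#'   `rejected` (TRUE when coverage <= 0.5).
#' @export
coverage <- function(records, pair, search_both_strands = TRUE) {
  if (nrow(records) == 0L) stop("empty record collection", call. = FALSE)
  ext <- extract_regions(records, pair,
                         search_both_strands = search_both_strands)
  frac <- mean(ext$matched)
  list(region = pair$region, coverage = frac, n = nrow(records),
       n_matched = sum(ext$matched), rejected = frac <= 0.5)
}

#' Write extraction results as FASTA plus a coordinates TSV
#'
#' Coordinates are 0-based half-open on the oriented source sequence.
#'
#' @param extractions data.frame from [extract_regions()].
#' @param fasta_path,coords_path output paths.
#' @return invisibly, the matched subset of `extractions`.
#' @export
write_extractions <- function(extractions, fasta_path, coords_path) {
  ok <- extractions[extractions$matched, , drop = FALSE]
  set <- Biostrings::BStringSet(ok$sequence)
  names(set) <- ok$id
  Biostrings::writeXStringSet(set, fasta_path, width = 20000L)
  utils::write.table(
    ok[, c("id", "region", "start", "end", "fwd_mismatches",
           "rev_mismatches", "orientation")],
    coords_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ok)
}
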