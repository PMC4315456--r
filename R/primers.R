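# Primer pairs delimiting 16S hypervariable regions.

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

is_iupac <- function(x) {
  all(strsplit(toupper(x), "")[[1]] %in% names(IUPAC_EXPANSION))
}

#' Construct a primer pair delimiting one hypervariable region
#'
#' Both primers are written 5'→3' on their own strand (the reverse primer on
#' the reverse strand, as in primer catalogues); extraction reverse-complements
#' the reverse primer before searching. Primers must be IUPAC DNA of length
#' at least 10.
#'
#' @param region region label, e.g. `"V3"` or `"V35"`.
#' @param forward,reverse IUPAC DNA primer sequences.
#' @param max_mismatches mismatches tolerated per primer (default 0;
#'   degenerate IUPAC bases already absorb catalogued primer variability).
#' @return a `primer_pair` list.
#' @export
primer_pair <- function(region, forward, reverse, max_mismatches = 0L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (nchar(forward) < 10 || nchar(reverse) < 10) {
    stop("primers must be at least 10 nt long", call. = FALSE)
  }
  if (!is_iupac(forward) || !is_iupac(reverse)) {
    stop("primers may only contain IUPAC DNA codes", call. = FALSE)
  }
  if (max_mismatches < 0) stop("max_mismatches must be >= 0", call. = FALSE)
  structure(list(region = region, forward = forward, reverse = reverse,
                 max_mismatches = as.integer(max_mismatches)),
            class = "primer_pair")
}

#' Built-in primer table for V2-V8 and combined regions
#'
#' Representative literature primer pairs for the individual hypervariable
#' regions V2-V8 and the combined regions V23, V34, V35, V45, V56, V67 and
#' V78 (a combined region pairs the forward primer of its first region with
#' the reverse primer of its last). V1 and V9 are deliberately absent: no
#' primer pair recovers them from a majority of reference sequences. The
#' table is data, not algorithm — override it with [read_primer_table()]
#' whenever your amplicons were produced with different primers.
#'
#' @return a data.frame with columns `region`, `forward`, `reverse`,
#'   `max_mismatches`.
#' @export
default_primer_table <- function() {
  f <- c(V2 = "AGTGGCGGACGGGTGAGTA",     # 104F
         V3 = "CCTACGGGAGGCAGCAG",       # 341F
         V4 = "GTGCCAGCMGCCGCGGTAA",     # 515F
         V5 = "AGGATTAGATACCCTGGTAGTCC", # 784F
         V6 = "CAACGCGAAGAACCTTACC",     # 967F
         V7 = "CAACGAGCGCAACCCT",        # 1100F
         V8 = "GGGCTACACACGYGCWAC")      # 1237F
  r <- c(V2 = "TGCTGCCTCCCGTAGGAGT",     # 338R
         V3 = "ATTACCGCGGCTGCTGG",       # 534R
         V4 = "GGACTACHVGGGTWTCTAAT",    # 806R
         V5 = "CCGTCAATTCMTTTRAGTTT",    # 926R
         V6 = "CGACAGCCATGCANCACCT",     # 1046R
         V7 = "ACGTCATCCCCACCTTCC",      # 1193R
         V8 = "GACGGGCGGTGTGTRCA")       # 1391R
  combos <- c(V23 = "V2.V3", V34 = "V3.V4", V35 = "V3.V5", V45 = "V4.V5",
              V56 = "V5.V6", V67 = "V6.V7", V78 = "V7.V8")
  region <- c(names(f), names(combos))
  forward <- c(unname(f),
               unname(f[sub("\\..*", "", combos)]))
  reverse <- c(unname(r),
               unname(r[sub(".*\\.", "", combos)]))
  data.frame(region = region, forward = forward, reverse = reverse,
             max_mismatches = 0L, stringsAsFactors = FALSE)
}

#' Read a primer table from TSV
#'
#' Expects a header line with columns `region`, `forward`, `reverse` and
#' optionally `max_mismatches` (default 0).
#'
#' @param path path to the TSV file.
#' @return a data.frame like [default_primer_table()].
#' @export
read_primer_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  need <- c("region", "forward", "reverse")
  if (!all(need %in% names(tab))) {
    stop("primer table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab$max_mismatches <- if ("max_mismatches" %in% names(tab)) {
    as.integer(tab$max_mismatches)
  } else 0L
  # validate through the constructor
  for (i in seq_len(nrow(tab))) {
    primer_pair(tab$region[i], tab$forward[i], tab$reverse[i],
                tab$max_mismatches[i])
  }
  tab[, c("region", "forward", "reverse", "max_mismatches")]
}

#' Look up one region's primer pair in a primer table
#'
#' @param region region label.
#' @param table a primer table data.frame (default the built-in table).
#' @return a `primer_pair`.
#' @export
get_primer_pair <- function(region, table = default_primer_table()) {
  i <- match(region, table$region)
  if (is.na(i)) {
    stop("no primer pair for region '", region, "'", call. = FALSE)
  }
  primer_pair(table$region[i], table$forward[i], table$reverse[i],
              table$max_mismatches[i])
}
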