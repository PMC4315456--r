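# Synthetic 16S-like reference generator: conserved primer sites flanking
# rank-structured variable cores, with a ground-truth manifest.

# One concrete ACGT instantiation of an IUPAC primer (first expansion
# letter per code, so the IUPAC primer always matches the planted site).
concretize_primer <- function(primer) {
  chars <- strsplit(toupper(primer), "")[[1]]
  paste(vapply(chars, function(b) IUPAC_EXPANSION[[b]][1], character(1)),
        collapse = "")
}

#' Describe a synthetic reference design
#'
#' The taxonomy is a balanced tree: `n_phyla` phyla, each with `n_classes`
#' classes, and so on down to `n_genera` genera per family with
#' `n_per_genus` sequences each. Every sequence carries each listed region
#' as a variable core flanked by concrete instances of that region's
#' primers; all flanks, primer sites and spacers are conserved across the
#' whole reference, so primer coverage is 1 by construction (unless
#' `corrupt_primer_fraction > 0`, which destroys the forward primer sites
#' of that fraction of sequences — for testing coverage accounting).
#'
#' Divergence rates are substitutions per site applied to the variable
#' cores along each edge of the taxonomy tree, chosen to mimic real 16S
#' structure: sister genera end up roughly 10% apart in their cores and
#' sequences within a genus roughly 98-99% identical.
#'
#' @param n_phyla,n_classes,n_orders,n_families,n_genera fan-out per rank.
#' @param n_per_genus sequences per genus.
#' @param regions region labels to plant (must exist in `primer_table`).
#' @param core_lengths named integer vector of core lengths per region.
#' @param divergence named rates for `phylum`, `class`, `order`, `family`,
#'   `genus` (edge above that rank's nodes) and `sequence` (leaf edges).
#' @param corrupt_primer_fraction fraction of sequences whose forward
#'   primer sites are overwritten with random bases.
#' @param primer_table primer table the design plants sites from.
#' @param seed integer seed; the whole fixture is deterministic given it.
#' @return a `fixture_design` list.
#' @export
fixture_design <- function(n_phyla = 3, n_classes = 2, n_orders = 2,
                           n_families = 2, n_genera = 3, n_per_genus = 5,
                           regions = c("V3", "V4"),
                           core_lengths = c(V3 = 150L, V4 = 207L),
                           divergence = c(phylum = 0.15, class = 0.08,
                                          order = 0.06, family = 0.05,
                                          genus = 0.05, sequence = 0.01),
                           corrupt_primer_fraction = 0,
                           primer_table = default_primer_table(),
                           seed = 1L) {
  fan <- c(n_phyla, n_classes, n_orders, n_families, n_genera, n_per_genus)
  stopifnot(all(fan >= 1), all(divergence >= 0), all(divergence <= 0.5),
            corrupt_primer_fraction >= 0, corrupt_primer_fraction <= 1,
            all(regions %in% primer_table$region),
            all(regions %in% names(core_lengths)))
  if (prod(fan) > 1e6) {
    stop("design would produce more than 1e6 sequences", call. = FALSE)
  }
  structure(list(n_phyla = n_phyla, n_classes = n_classes,
                 n_orders = n_orders, n_families = n_families,
                 n_genera = n_genera, n_per_genus = n_per_genus,
                 regions = regions, core_lengths = core_lengths,
                 divergence = divergence,
                 corrupt_primer_fraction = corrupt_primer_fraction,
                 primer_table = primer_table, seed = seed),
            class = "fixture_design")
}

# Substitute each core position with probability `rate` (never silent);
# runs inside the caller's seeded RNG stream.
mutate_core <- function(core, rate) {
  if (rate == 0) return(core)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(core, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic reference from a design
#'
#' Builds a root set of variable cores, then descends the taxonomy tree
#' applying the per-rank substitution rate to the cores only (conserved
#' flanks, spacers and primer sites are untouched), and assembles one
#' sequence per leaf. Deterministic given the design seed.
#'
#' @param design a [fixture_design()].
#' @return a `fixture_reference` list: `records` (a reference data.frame as
#'   from [read_reference()]), and `manifest` with `coordinates` (data.frame
#'   `id`, `region`, `start`, `end` — 0-based half-open span of each core
#'   between its primer sites), `group_counts` (named integer per rank),
#'   `corrupted_ids`, and the `design`.
#' @export
generate_reference <- function(design) {
  stopifnot(inherits(design, "fixture_design"))
  regions <- design$regions
  pairs <- lapply(regions, get_primer_pair, table = design$primer_table)
  names(pairs) <- regions
  with_seed(design$seed, {
    flank5 <- random_dna(25)
    flank3 <- random_dna(25)
    spacer <- random_dna(30)
    fwd_sites <- vapply(pairs, function(p) concretize_primer(p$forward),
                        character(1))
    rev_sites <- vapply(pairs, function(p) revcomp(concretize_primer(p$reverse)),
                        character(1))
    root_cores <- vapply(regions, function(rg) {
      random_dna(design$core_lengths[[rg]])
    }, character(1))

    # core coordinates are design constants (cores keep their length)
    coords <- list()
    pos <- nchar(flank5)
    for (ri in seq_along(regions)) {
      pos <- pos + nchar(fwd_sites[[ri]])
      core_start <- pos
      pos <- pos + unname(design$core_lengths[[regions[ri]]])
      coords[[regions[ri]]] <- c(start = core_start, end = pos)
      pos <- pos + nchar(rev_sites[[ri]])
      if (ri < length(regions)) pos <- pos + nchar(spacer)
    }

    assemble <- function(cores) {
      parts <- flank5
      for (ri in seq_along(regions)) {
        parts <- c(parts, fwd_sites[ri], cores[ri], rev_sites[ri])
        if (ri < length(regions)) parts <- c(parts, spacer)
      }
      paste(c(parts, flank3), collapse = "")
    }

    div <- design$divergence
    fan <- list(phylum = design$n_phyla, class = design$n_classes,
                order = design$n_orders, family = design$n_families,
                genus = design$n_genera)
    prefix <- c(phylum = "Phy", class = "Cla", order = "Ord",
                family = "Fam", genus = "Gen")

    rows <- list()
    descend <- function(cores, depth, path, lineage) {
      rank_names <- names(fan)
      if (depth > length(rank_names)) {
        for (s in seq_len(design$n_per_genus)) {
          leaf_cores <- vapply(cores, mutate_core, character(1),
                               rate = div[["sequence"]])
          rows[[length(rows) + 1L]] <<- c(
            list(sequence = assemble(leaf_cores)), lineage)
        }
        return(invisible(NULL))
      }
      rank <- rank_names[depth]
      for (i in seq_len(fan[[rank]])) {
        child_cores <- vapply(cores, mutate_core, character(1),
                              rate = div[[rank]])
        child_path <- c(path, i)
        child_lineage <- lineage
        child_lineage[[rank]] <- paste0(prefix[[rank]],
                                        paste(child_path, collapse = "."))
        descend(child_cores, depth + 1L, child_path, child_lineage)
      }
    }
    descend(root_cores, 1L,
            integer(0),
            list(kingdom = "Bacteria", phylum = "", class = "", order = "",
                 family = "", genus = "", species = ""))

    n <- length(rows)
    ids <- sprintf("seq%04d", seq_len(n))
    records <- data.frame(
      id = ids,
      sequence = vapply(rows, `[[`, character(1), "sequence"),
      stringsAsFactors = FALSE)
    for (rk in TAXONOMIC_RANKS) {
      records[[rk]] <- vapply(rows, `[[`, character(1), rk)
    }

    corrupted_ids <- character(0)
    if (design$corrupt_primer_fraction > 0) {
      n_corrupt <- round_half_up(design$corrupt_primer_fraction * n)
      corrupt <- sample(seq_len(n), n_corrupt)
      corrupted_ids <- ids[corrupt]
      for (i in corrupt) {
        s <- records$sequence[i]
        for (ri in seq_along(regions)) {
          site_start <- coords[[regions[ri]]][["start"]] -
            nchar(fwd_sites[ri])  # 0-based
          junk <- random_dna(nchar(fwd_sites[ri]))
          substr(s, site_start + 1L,
                 site_start + nchar(fwd_sites[ri])) <- junk
        }
        records$sequence[i] <- s
      }
    }

    coordinates <- do.call(rbind, lapply(regions, function(rg) {
      data.frame(id = ids, region = rg,
                 start = unname(coords[[rg]]["start"]),
                 end = unname(coords[[rg]]["end"]),
                 stringsAsFactors = FALSE)
    }))
    group_counts <- vapply(CLASSIFICATION_RANKS, function(rk) {
      length(unique(records[[rk]][records[[rk]] != ""]))
    }, integer(1))

    structure(list(records = records,
                   manifest = list(coordinates = coordinates,
                                   group_counts = group_counts,
                                   corrupted_ids = corrupted_ids,
                                   design = design)),
              class = "fixture_reference")
  })
}

#' Write a synthetic reference to disk
#'
#' Emits FASTA + taxonomy TSV (readable by [read_reference()]) and the
#' ground-truth manifest as JSON.
#'
#' @param fixture a `fixture_reference` from [generate_reference()].
#' @param dir output directory (created if missing).
#' @return invisibly, a named list of the paths written.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(dir, "reference.fasta"),
                taxonomy = file.path(dir, "taxonomy.tsv"),
                manifest = file.path(dir, "manifest.json"))
  write_reference(fixture$records, paths$fasta, paths$taxonomy)
  m <- fixture$manifest
  jsonlite::write_json(
    list(coordinates = m$coordinates,
         group_counts = as.list(m$group_counts),
         corrupted_ids = m$corrupted_ids,
         design = m$design[setdiff(names(m$design), "primer_table")],
         seed = m$design$seed),
    paths$manifest, auto_unbox = TRUE, digits = NA, dataframe = "columns",
    pretty = TRUE)
  invisible(paths)
}

#' Simulate amplicon reads from a synthetic reference
#'
#' Reads are the planted region cores (primer sites trimmed) with
#' substitution errors injected at `mutation_rate`, plus a truth table
#' mapping each read to its source lineage.
#'
#' @param fixture a `fixture_reference`.
#' @param region planted region label.
#' @param n_per_sequence reads per source sequence (default 1).
#' @param mutation_rate per-base substitution probability (default 0).
#' @param seed integer seed for the error injection.
#' @param ids source sequence ids to draw from (default all).
#' @return a list: `reads` (named character vector) and `truth`
#'   (data.frame `query_id`, `source_id`, plus lineage rank columns).
#' @export
generate_reads <- function(fixture, region, n_per_sequence = 1,
                           mutation_rate = 0, seed = 1L, ids = NULL) {
  coords <- fixture$manifest$coordinates
  coords <- coords[coords$region == region, , drop = FALSE]
  if (nrow(coords) == 0) {
    stop("region '", region, "' is not planted in this fixture",
         call. = FALSE)
  }
  if (!is.null(ids)) coords <- coords[coords$id %in% ids, , drop = FALSE]
  if (n_per_sequence < 1) {
    return(list(reads = character(0),
                truth = data.frame(query_id = character(0),
                                   source_id = character(0))))
  }
  rec <- fixture$records[match(coords$id, fixture$records$id), ]
  cores <- substr(rec$sequence, coords$start + 1L, coords$end)
  reads <- character(0)
  src <- character(0)
  for (rep_i in seq_len(n_per_sequence)) {
    r <- cores
    names(r) <- sprintf("%s_%s_r%d", coords$id, region, rep_i)
    reads <- c(reads, r)
    src <- c(src, coords$id)
  }
  if (mutation_rate > 0) {
    reads <- inject_mutations(reads, rate = mutation_rate, seed = seed)
  }
  truth <- cbind(
    data.frame(query_id = names(reads), source_id = src,
               stringsAsFactors = FALSE),
    fixture$records[match(src, fixture$records$id), TAXONOMIC_RANKS])
  rownames(truth) <- NULL
  list(reads = reads, truth = truth)
}
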