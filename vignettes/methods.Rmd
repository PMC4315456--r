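---
title: "Methods: per-rank random forests for 16S hypervariable regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-rank random forests for 16S hypervariable regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplicontax)
```

This vignette documents the model behind `amplicontax`, the choices made
where the design was genuinely open, and what the synthetic test data can
and cannot tell you about behaviour on real references.

## The classification model

A 16S amplicon read from a known hypervariable region is represented as a
vector of overlapping k-mer frequencies,

$$f_w = \frac{\text{count of } w}{\text{number of valid windows}},
\qquad w \in \{A,C,G,T\}^k,$$

and classified by one random forest per taxonomic rank, phylum through
genus. Each forest is an ordinary bagged ensemble
(`randomForest`): each tree grows on a bootstrap sample (about two thirds
of the data in-bag), and the out-of-bag (OOB) remainder provides an
internal error estimate without a separate validation set. Ranks are
trained and predicted *independently* — the genus forest never sees the
phylum prediction. This mirrors how the training groups are formed (all
sequences sharing a taxon name at a rank form one class) and keeps label
spaces honest, at the cost of occasional hierarchically inconsistent
outputs; `classify_reads(..., consistent = TRUE)` optionally repairs
these by walking down from phylum and restricting each rank's candidates
to children of the chosen parent in the training taxonomy. The default
reports ranks as predicted, because consistency repair discards
information when an upper rank is itself wrong.

K-mers are *plain*, not canonicalized: the 4-mer space has all 256
words, and a sequence and its reverse complement featurize differently.
Orientation therefore matters; `orient_reads()` recovers it by
classifying both orientations at the phylum rank and keeping the one with
the stronger top vote (ties keep forward).

## Parameters and their defaults

* **k = 4** (word length; range 2–8). Smaller k underfits; larger k
  multiplies the feature space (4ᵏ) and the training cost for marginal
  gain. 256 variables is the sweet spot for ~100–550 nt regions.
* **ntree = 1000.** OOB error declines with forest size and has
  essentially saturated by 1000 trees; the test suite and examples use
  100–200 trees, which is plenty at fixture scale.
* **mtry = ⌊√4ᵏ/2⌋** (8 for k = 4), the number of candidate variables per
  split. `tune_mtry()` refines it with a multiplicative walk (step factor
  1.5, rounding half-up, clipped to [1, p]): starting from the default it
  moves down, then up, continuing in a direction while the relative OOB
  improvement over the best error so far exceeds 0.02. The full trace is
  returned; the chosen mtry is the visited value with minimal error,
  ties to the first visited. The error criterion is OOB by default; a
  10-fold cross-validated criterion is available via
  `error_estimate = "cv"` for users who prefer a fold-based estimate,
  but OOB is the default because it is what the tuning walk's step/improve
  semantics were designed around and costs nothing extra.
* **max_mismatches = 0** per primer in extraction. Degenerate IUPAC bases
  in the primers already absorb the catalogued variability of the
  conserved sites, and exact matching is reproducible across databases;
  the tolerance is configurable per primer pair.
* **confidence_threshold = 0** in classification: the top vote is always
  reported, with its fraction, and thresholding is left to the caller
  (a taxon below threshold is reported `Unclassified` at that rank *and
  below*, since a discarded parent makes the children meaningless).

## Numerical and procedural choices

* **Primer matching** is IUPAC-intersection Hamming scoring over every
  window, no indels; among windows with the fewest mismatches the
  leftmost wins (determinism). Empty sequences or primers longer than the
  sequence are a no-match, not an error. If the forward strand fails, the
  reverse complement of the source is searched and results are reported
  in primer orientation.
* **Extraction** keeps the span strictly between the primer sites; the
  primers themselves are trimmed everywhere (training and query), so
  invariant primer bases never masquerade as features. A zero-length
  span is a no-match with reason `empty_region`.
* **Ambiguous bases** (N and friends) in a sequence: any window containing
  one is dropped from both numerator and denominator of the k-mer
  frequencies. Reads with no valid window at all are `Unclassified` with
  reason `too_short`.
* **Global identity** for dereplication is matching columns over the
  longer length. Equal-length pairs are scored by Hamming identity;
  pairs whose length difference alone forces identity below threshold are
  rejected without alignment; remaining unequal-length pairs get an
  end-gap-free (overlap) alignment. Near 1.0 — the only thresholds used
  here — virtually all merges are substitution-only, which Hamming
  handles exactly; re-implementing CD-HIT's word filters would add speed,
  not correctness, and is out of scope.
* **Greedy clustering** processes sequences longest-first (stable in
  input order), each joining the first cluster whose representative it
  matches; the founder (longest member) represents the cluster.
* **Train/test splitting** draws `round(0.10 × size)`, minimum one,
  members from every cluster with at least two members; singletons go
  wholly to train. A global exact-fraction split would break the
  per-cluster structure the held-out set is meant to respect.
* **Error injection** is substitution-only: each site flips with the
  nominal probability to one of the three *other* bases, so the realized
  rate is exactly the nominal rate in expectation and length is
  preserved. Indels are deliberately excluded — the fixed-length regions
  and the k-mer representation make substitutions the relevant error
  mode.
* **Metrics** are computed one-vs-rest per rank group and macro-averaged
  (unweighted) across groups; any metric with a zero denominator is
  undefined, excluded from the average, and counted. MCC uses the
  product-of-sums denominator in double precision (sums are cast before
  multiplying to avoid integer overflow on large groups).
* **Sequences with incomplete lineages**: grouping at a rank excludes
  records unlabelled there (counted, not dropped silently); lineages
  violating the prefix property (a named genus under an unnamed family)
  are truncated at the first gap on ingest, with a warning, because
  per-rank grouping requires consistent prefixes.
* **Rare labels** (fewer than two training sequences) are dropped with a
  warning by default (`rare_label_action = "error"` to refuse instead):
  a single example cannot contribute an out-of-bag estimate and tends to
  produce degenerate votes.

## The synthetic reference generator

`fixture_design()` describes a balanced taxonomy (default 3 phyla × 2
classes × 2 orders × 2 families × 3 genera × 5 sequences = 360 records)
whose sequences are conserved flanks, concrete primer sites and spacers
around variable cores (default V3 at 150 nt and V4 at 207 nt, matching
typical region lengths). Cores mutate along the tree edges at per-rank
rates (defaults 0.15/0.08/0.06/0.05/0.05 from phylum to genus and 0.01
within a genus), so sister genera differ by roughly 10% in their cores
and within-genus sequences by ~2% — about the identity structure of real
genera — while primer sites stay bit-identical, giving coverage 1.0 by
construction. An option corrupts the primer sites of a stated fraction
of sequences so coverage accounting can be tested separately.

What the generator does **not** emulate: the extreme class imbalance of
real databases (thousands of rank groups with heavy tails), chimeras,
secondary-structure-driven conservation *inside* variable regions,
PCR/primer bias, indel sequencing errors and taxonomic mislabelling.
Passing the planted-signal tests therefore shows the pipeline is
correct and recovers structure that is present; it does not predict the
accuracy achievable on a real reference, which is bounded by those
harder properties of real data.

## Problem sizes used by the test suite

The suite favours small, fully checkable instances: oracle comparisons
on sequences up to 500 nt, clustering oracles at n ≤ 50, forests of
30–200 trees on tens-to-hundreds of rows, and one end-to-end experiment
on the default 360-sequence fixture (five seeds, one held-out sequence
per genus, 200 trees per forest, reads at 0% and 1% substitution error).
These sizes were chosen as the smallest at which each property is
non-trivially exercised.

## Known limitations

* Primer matching is substitution-only; an indel in a conserved site
  defeats extraction (use a higher-level aligner upstream if your data
  needs that).
* Species rank is not modelled (training groups run phylum → genus).
* Dereplication is exact/greedy identity, not CD-HIT's banded-alignment
  heuristics; at thresholds far below 0.999 it will be slow on large
  inputs.
* Forest training is single-threaded and in-memory; a full
  million-sequence reference is out of desk-scale reach and should be
  dereplicated and chunked per rank group first.
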