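Package: amplicontax
Title: Random-Forest Taxonomic Classification of 16S rRNA Hypervariable Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts 16S rRNA hypervariable regions from reference sequences
    by fuzzy IUPAC primer matching, featurizes them as normalized k-mer
    frequency vectors, trains one random forest per taxonomic rank
    (phylum through genus) with out-of-bag mtry tuning and permutation
    importance pruning, assigns taxonomy to short amplicon reads with
    QIIME-compatible output, and evaluates classifiers with macro-averaged
    sensitivity, specificity, precision, accuracy, G-mean, F-measure and
    Matthews correlation. Includes a synthetic reference generator with
    planted primer sites and a rank-structured taxonomy so the whole
    pipeline is testable without downloading a reference database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
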