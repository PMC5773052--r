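Package: locrex
Title: Relation Extraction of Protein Subcellular Localizations from Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts protein-to-subcellular-localization relationships from
    biomedical abstracts and aggregates them into document-level, normalized
    GO Cellular Component annotations for database curation. Candidate
    protein-location mention pairs co-occurring in the same sentence are
    classified with a linear support vector machine over sparse lexical,
    part-of-speech and dependency-parse shortest-path n-gram features,
    selected by an L1-penalized linear classifier. Includes a pluggable
    named-entity tagger contract with a built-in dictionary tagger and GO
    post-filters, a deterministic template-based fixture-corpus generator,
    GO ontology handling (is_a/part_of descendant closure, hierarchy-aware
    relation deduplication), and a normalized-relation evaluation harness
    with precision/recall/F and bootstrap standard errors under 5-fold
    60/20/20 document-level cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
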