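Package: denovotax
Title: Taxonomic Profiling of Microbial Communities from De Novo Sequenced Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns de novo sequenced peptides (plus scrambled decoy
    sequences) against protein reference databases and derives consensus
    taxonomies per peptide with three lowest-common-ancestor algorithms
    (conventional, frequency-weighted, and bitscore-based). Aggregates the
    per-peptide assignments into a community composition with decoy-based
    false-positive control, evaluates the spectral quality and database
    coverage of companion database-search experiments, and builds or
    complements protein reference databases from the identified taxa. Also
    includes a de novo sequencing-error simulator (equal-mass substitutions,
    fragment inversions, codon-level mutations) used to exercise and
    validate short-peptide alignment parameters, and synthetic community
    generators so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
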