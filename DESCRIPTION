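Package: xmeprofiler
Title: Label-Free Proteomic Profiling of Xenobiotic-Metabolising Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a comparative label-free
    proteomic profiling workflow for xenobiotic-metabolising enzymes
    (XMEs) in human skin, liver and in vitro skin models. Provides
    in-silico tryptic digestion, exact substring peptide-to-protein
    mapping with uniqueness classification, keyword-driven XME selection
    from protein names (accept/reject lists plus word filters),
    shared-peptide protein-group consolidation with root-name
    derivation, detection calling (at least two distinct tryptic
    peptides in at least two donors), summed-intensity fold differences
    with limit-of-detection substitution, exact Mann-Whitney rank
    testing, peptide-count profiles for model comparison, and spike-in
    limit-of-detection calibration with bounded-ratio arithmetic. A
    synthetic-data generator emulates ion-trap identification tables
    with known ground truth so every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
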