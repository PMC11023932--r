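Package: pegquant
Title: Quantification of Prime Editing Outcomes, Off-Target Flap Conversion,
    Reporter Screen Enrichment and pegRNA Fragment Integrity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Read-level quantification of prime-editing outcomes in amplicon
    sequencing data around the pegRNA nick (intended edits with and without
    indels, indels without the intended edit), diagnostic-nucleotide scoring
    of off-target prime editing from the pegRNA-encoded 3' DNA flap,
    enrichment statistics for pooled CRISPRi reporter screens with
    non-targeting pseudogene nulls and empirical false discovery rates, and
    integrity binning of pegRNA-derived small-RNA fragments. Includes seeded
    synthetic-data generators for amplicon reads, screen count tables and
    pegRNA fragments so every stage of the pipeline can be exercised and
    calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    data.table,
    methods,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
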