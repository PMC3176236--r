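Package: mitoarch
Title: Comparative Architecture Analysis of Animal Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of animal mitochondrial genome
    architecture: parsing and validation of annotation tables and GenBank-style
    feature tables, circular intergenic spacer computation, nucleotide
    composition and AT/GC strand-skew statistics, signed circular gene-order
    extraction and comparison against arthropod and pancrustacean ground
    patterns (junction-pattern classification, breakpoint counts, inverted-block
    detection, one-step tandem-duplication-random-loss feasibility), tandem
    repeat detection in control regions, a constrained cloverleaf model for
    truncated mitochondrial tRNAs, multi-genome junction-pattern surveys, and a
    seeded synthetic-genome generator with full ground truth for offline
    verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
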