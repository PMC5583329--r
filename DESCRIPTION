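Package: introscape
Title: Comparative Gene Architecture, Intron Evolution and Microsynteny Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of gene architectures in gene
    families: projection of intron positions onto reference codon numbering
    with phase letters (e.g. "192a"), comparison and in-silico editing of
    exon/intron architectures, distance-based (neighbor-joining) trees,
    Dollo-parsimony placement and dating of intron gain/loss events on
    species trees, duplication-node detection by species overlap,
    microsynteny comparison of flanking-gene neighborhoods, and serpin
    sequence-feature annotation (reactive-center loop, hinge class,
    ER-retention motifs, alignment conservation). Includes a seeded
    gene-family evolution simulator emitting standard-format fixtures with
    a ground-truth event log, so every pipeline stage can be validated
    end-to-end on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
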