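Package: etipseq
Title: Analysis of Topoisomerase IIbeta Action Sites from Two-Fraction
    Immunoprecipitation Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping and characterising topoisomerase IIbeta action
    sites ("toposites") from etoposide-mediated topoisomerase
    immunoprecipitation sequencing (eTIP-seq). The package calls and classifies
    toposites (Ts1/Ts2/Ts3) from paired P1/P2 fraction libraries, analyses
    G-/T-segment ligation chimeras (proximal vs distal strand passage, read
    orientation logic), classifies terminal sequence homology of distal-passage
    chimera ends into direct or inverted repeats by two-strand local alignment,
    detects toposite and chimera clusters and their hotspot integration, and
    quantifies chromatin condensation from 3D nuclear image stacks. A synthetic
    data generator with full ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    EBImage,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
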