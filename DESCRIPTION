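Package: dinoPKS
Title: Polyketide Synthase Gene Characterization for Dinoflagellate Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-survey characterization of polyketide synthase
    (PKS) and hybrid NRPS-PKS genes in dinoflagellates such as Symbiodinium
    minutum. Provides degenerate protein-motif scanning with catalytic
    active-site verification (ketosynthase DTACSS and companion His/Lys
    residues), domain-architecture parsing and gene classification
    (single-KS, multifunctional PKS, hybrid NRPS-PKS), assembly-line module
    decomposition with adenylation-domain specificity-code extraction,
    spliced-leader trans-splicing read trimming with transcription-start-site
    clustering, monoisotopic mass and adduct m/z matching of polyketide
    metabolites at milli-mass-unit tolerance, distance-based ketosynthase
    clade assignment by neighbor joining, and synthetic-data generators so
    that the whole workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
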