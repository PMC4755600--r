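Package: modmt
Title: Modular Metallothionein Sequence, Gene Structure and Metal
    Stoichiometry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterization toolkit for long, modular fungal
    metallothioneins (MTs). Screens protein sequences for MT-likeness
    (cysteine fraction, absence of aromatics), decomposes polypeptides
    into tandem Cys-box modules by gap-signature scanning and dynamic
    programming, reconstructs exon/intron gene models by spliced
    alignment of a cDNA against a genomic scaffold under canonical GT/AG
    intron constraints, scans promoters for TATA and metal-response
    elements, assigns deconvoluted native ESI-MS peaks to metal/sulfide
    stoichiometries, converts ICP-AES element concentrations to
    metal-per-protein ratios via sulfur-based protein quantitation,
    predicts Cu(I) cluster capacity from module architecture with an
    additive per-box model, and normalizes copper-tolerance growth
    assays. Includes seeded generators for synthetic proteins, genes,
    peak lists and growth tables with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
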