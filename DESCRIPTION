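Package: epitiler
Title: Linear B-Cell Epitope Mapping from Overlapping Peptide Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for microarray-based linear B-cell epitope
    mapping of a protein monomer with overlapping peptide tiles. Tiles a
    mature protein sequence into 15-mers with 14-residue overlap and neutral
    GS flanks, models per-subject array scans (serum and pre-serum background)
    as a SummarizedExperiment, calls seropositive peptides against a 2x
    background cutoff, reduces overlapping positive peptides to minimal
    consensus epitopes per subject and harmonizes them across a cohort,
    derives serology quantities (arbitrary units against a reference serum,
    empirical percentile cutoffs, net optical density, antiphospholipid
    positivity), runs the nonparametric association battery used in
    seroprevalence studies, and quantifies neutrophil functional assays
    (oxidative-burst chemiluminescence area under curve, 3D chemotaxis track
    metrics, extracellular-DNA release). A synthetic-data module generates
    every input with planted ground truth, including a frozen fixture cohort
    of 42 patients and 11 healthy donors. Ships the 206-residue mature human
    C-reactive protein monomer as the reference antigen fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
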