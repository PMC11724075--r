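Package: DimerScreen
Title: Screening Cascade for Small-Molecule Receptor-Dimerization Agonists
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of the computational cascade used to
    discover small-molecule agonists of receptor dimerization (ERBB4/NRG1
    class assays) from a high-throughput screen: median-polish plate
    correction and B-score normalization with top-N triage and
    mean-plus-3-SD confirmation hit calling; maximum-common-substructure
    pharmacophore mining with k-means pattern clustering and fold-enrichment
    scoring against a reference library; circular-fingerprint random-forest
    hit expansion; four-parameter logistic EC50/IC50 and potentiation
    pharmacology; and a seeded compact-watershed cardiomyocyte
    cross-sectional-area segmentation pipeline. A synthetic-data module
    generates plates, compound libraries, dose-response tables and
    two-channel cell images with ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB,
    EBImage,
    tiff,
    minpack.lm,
    ranger,
    igraph,
    jsonlite,
    pROC,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr,
    rmarkdown
SystemRequirements: OpenBabel (obabel on the PATH) for SMARTS substructure
    matching and SMILES canonicalization.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, CellBasedAssays, Cheminformatics, Classification
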