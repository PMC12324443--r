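Package: crosslinkR
Title: Quantitative Crosslinking Mass Spectrometry Analysis and
    Structure-Based Restraint Validation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for in-cell photo-crosslinking mass spectrometry
    (XL-MS) studies of protein assemblies. Implements label-free AP-MS
    differential enrichment (completeness filtering, normalization, mixed
    MAR/MNAR imputation, Welch tests with Benjamini-Hochberg correction),
    hierarchical target-decoy false discovery rate control at the
    residue-pair and protein-protein interaction levels with PPI boosting,
    mapping of crosslink-derived Calpha-Calpha distance restraints onto
    structural ensembles (PDB/mmCIF) with satisfaction classification and
    overlength-cluster detection, confidence scoring of predicted complexes
    (ipTM/pTM) validated against crosslink restraints, and seeded synthetic
    generators (toy complexes, SDA-chemistry crosslink simulation, quant
    matrices, candidate score sets) providing ground truth for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    bio3d,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
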