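Package: plasticmine
Title: Mining Metagenomes for Plastic-Degrading Enzyme Homologues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for surveying the plastic-degrading
    potential of environmental microbiomes. Builds an identity-stratified
    library of profile scoring models from a curated catalog of
    experimentally verified plastic- and plasticizer-degrading enzymes,
    scores metagenomic gene catalogs against the library with
    decoy-calibrated E-values, filters hits by per-model precision-recall
    calibration against a negative-control (gut-like) catalog, aggregates
    filtered hits into per-sample and per-dataset summaries, and relates
    hit abundance to habitat structure and geolocated plastic-pollution
    surveys (Box-Cox z-score pooling, haversine nearest-point matching,
    Spearman correlation, Siegel repeated-median trend fits). Includes a
    synthetic-data generator with controllable ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    geosphere,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
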