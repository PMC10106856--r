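Package: centroscape
Title: Centromere and Pericentromere Repeat Landscape Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising the repeat landscape of plant
    centromeres and pericentromeres: satellite-probe mapping and
    sliding-window density tracks, signal-based compartment boundary
    calling, full-length LTR retrotransposon insertion-time dating from
    5'/3' LTR divergence (JC69 or K2P corrected), nested-insertion
    detection, windowed sequence-identity heatmaps, and an
    occurrence-filter pipeline for discovering novel pericentromeric
    repeats from element self-alignment. Includes a synthetic chromosome
    simulator with planted ground truth (telomeres, satellite arrays,
    aged and nested LTR insertions, a hidden repeat) for end-to-end
    validation of every step.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    knitr
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
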