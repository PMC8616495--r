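Package: aggquant
Title: Quantification of Anchorage-Independent Cancer Cell Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify anchorage-independent aggregation of cancer
    cells from bright-field time-lapse z-stack movies and to relate the
    resulting aggregation parameters to gene expression. Provides a
    segmentation pipeline (focus fusion of z-stacks, morphological background
    subtraction, contrast enhancement, automated thresholding and connected
    component analysis), extraction of aggregation kinetic parameters
    (normalized area at 2 h, area under the aggregation curve, aggregate
    circularity), sparse partial least squares to select genes associated
    with those parameters, and a Connectivity-Map-style weighted enrichment
    score (wtcs, ncs, tau) to compare the selected gene signatures with a
    perturbagen signature library. A synthetic-data module generates
    aggregation movies, expression panels and signature libraries with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
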