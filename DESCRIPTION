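Package: plantatlas
Title: Marker Specificity, Annotation and Imaging-Panel Design for
    Multi-Organ Single-Nucleus Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for multi-organ single-nucleus and spatial
    transcriptomic atlases of plants. Implements nucleus- and spot-level
    quality filtering, per-cluster pseudobulk TPM aggregation, cluster
    marker detection by Wilcoxon rank-sum test, cross-organ classification
    of markers into organ-by-cell-type unique versus shared genes, curated
    marker-list cell-type enrichment scoring, co-expression (polarity
    positive) nucleus calling, exclusive marker-set overlap quantification,
    and expression-budgeted imaging (MERFISH) gene-panel design. Ships a
    negative-binomial multi-organ atlas simulator with planted marker
    classes and known ground truth so the full pipeline is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
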