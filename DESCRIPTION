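Package: lmarel
Title: Inter-Rater Reliability for Graph-Structured Movement Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing inter-rater reliability of annotations produced
    by traversing a directed decision graph, as used in Laban Movement Analysis
    (LMA) coding of movement observations. Provides a decision-graph data model
    with path-length equalization (trimming), a path-overlap difference measure
    between answer sequences, Krippendorff's alpha with this custom metric under
    four strategies for combining two ranked annotation rounds (round 1 only,
    order-dependent, order-independent, and an agreement-maximizing "R optimal"
    selection), per-gesture and per-category subset reliability, individual
    rater similarity to the modal annotation, viewing-behavior summaries, and a
    configurable multi-rater noise simulator for generating synthetic annotation
    datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
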