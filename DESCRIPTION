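Package: drugatlas
Title: Drug Atlas Construction and Drug-Combination Synergy Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the dissimilarity of single-drug effects across cancer
    cell-line panels (cosine dissimilarity of 1-AUC response vectors,
    hierarchical clustering, cophenetic distances), lays the resulting drug
    dendrogram out as a Voronoi treemap ("drug atlas"), predicts pairwise
    drug synergy with logistic models combining drug distance, normalized
    sensitivity and mutation-target information, scores experimental
    checkerboard viability matrices with an n-drug combination index
    (median-effect principle), and enumerates multi-drug candidates from
    dual-synergy graphs. Includes a ground-truth synthetic-data generator
    emulating process-structured drug-response panels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    mclust,
    withr
Config/testthat/edition: 3
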