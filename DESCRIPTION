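Package: netmark
Title: Network-Based Subnetwork Marker Discovery for Two-Class
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Identifies phenotype-discriminative subnetwork markers by
    integrating a two-class gene-expression matrix with an undirected
    protein-protein interaction network: per-gene z-scoring, greedy
    seed-expansion search scored by the mutual information between binned
    subnetwork activity and the phenotype, three permutation-test
    significance filters, a patient-half resampling consensus over
    repeated runs, and cross-validated classification of subnetwork
    activity with a decision tree and a radial-basis-function network.
    Ships a differential-expression hierarchical-clustering baseline for
    comparison and a synthetic-data generator with planted modules and
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    rpart,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    limma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
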