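Package: mirflow
Title: MicroRNA-Disease Association Prediction by Maximum Network Information Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts microRNA-disease associations by assembling a weighted
    heterogeneous microRNAome-phenome network from microRNA functional
    similarity, disease semantic and phenotypic similarity, and known
    association data (reweighted by microRNA family and genomic cluster
    co-association), and ranking candidates for a query node by the maximum
    information flow they receive, computed with an integer push-relabel
    maximum-flow algorithm. Includes disease semantic similarity over MeSH-style
    tree numbers via information content, target-overlap microRNA similarity,
    leave-one-out and ab initio cross-validation with rank-ratio ROC and
    precision-recall curves, permutation and ablation experiments, parameter
    grid search, hypergeometric enrichment, rank-average ensembling, and a
    self-contained synthetic benchmark generator with planted module structure.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
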