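Package: genembed
Title: Functional Gene Embeddings from Omics Matrices and Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and benchmarking of functional gene embeddings.
    Learns a shared gene embedding from heterogeneous gene-by-sample omics
    matrices with dataset-specific missing genes by variational deep tensor
    factorization with gradient-reversal domain adaptation, and from
    evidence-channel protein-interaction networks by biased random-walk
    (node2vec-style) and personalized-PageRank embeddings. Includes a seeded
    synthetic-data generator with planted latent gene function and
    publication-bias structure, and a downstream evaluation suite: gene-list
    classification with gradient-boosted trees, multi-label phenotype
    prediction, rare-variant gene recall, leave-one-chromosome-out GWAS
    z-score regression with Cholesky whitening, and publication-bias
    stratification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    glmnet,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
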