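Package: spectralimpute
Title: Spectral-Clustering-Guided Weighted Nearest-Neighbour Imputation for
    Gene Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Imputation of missing values in gene-expression matrices
    (genes x samples) by spectral clustering of genes on a Gaussian
    similarity graph followed by cluster-restricted, inverse-distance
    weighted top-K' nearest-neighbour estimation.  Includes the five
    classical local imputers used as baselines (KNNImpute, SKNNImpute,
    IKNNImpute, LLSImpute, SLLSImpute), a replicate RMSE benchmarking
    protocol with MCAR and MAR artificial-missingness injection, readers
    for delimited expression tables and GEO GDS SOFT files, and a
    synthetic generator of block-structured expression data for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
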