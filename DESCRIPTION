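Package: EpiSOM
Title: N-Way SNP Interaction Testing with Cluster-Guided Binary Encoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-step framework for the efficient detection of 2-SNP and
    3-SNP (epistatic) interactions in case/control studies with categorical
    genotype data. Per-SNP quality control (missingness, minor allele
    frequency, optional Hardy-Weinberg equilibrium) is followed by Random
    Forest feature selection (Mean Decrease in Gini), clustering of subjects
    with a self-organizing map for nominal categorical data (Hamming
    distance, mode-valued prototypes, cross-validated map-size selection),
    and a cluster-mode binary re-encoding of the genotypes that reduces the
    degrees of freedom of exhaustive interaction tests. Interactions are
    tested both by logistic regression with product terms and by a
    chi-square decomposition of the omnibus joint-genotype association,
    with permutation-based (max-T or per-test) multiple-testing adjustment.
    A synthetic-data module generates Hardy-Weinberg genotypes with latent
    cluster profiles and planted interaction effects for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
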