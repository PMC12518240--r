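Package: phenodes
Title: Phenotype Classification from Microbiome Count Tables with Dynamic
    Ensemble Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for binary phenotype classification from
    16S rRNA amplicon (ASV/OTU) count tables. Implements compositional
    preprocessing (pseudocount, total-sum scaling, centred log-ratio
    transform), same-class compositional CutMix augmentation for class
    balancing, consensus recursive feature elimination across three estimator
    families, a tuned pool of five base classifiers, four dynamic ensemble
    selection rules (DES-P, DES-Clustering, KNORA-E, KNORA-U) built from
    scratch, and permutation-based comparison of ROC curves (paired and
    unpaired rank tests). Ships a synthetic count-table generator so the whole
    pipeline is testable without external data, plus a small command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    glmnet,
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
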