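Package: hcg
Title: Hierarchical DNA-Level Classification of Gastric Cancer Molecular Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits and evaluates hierarchical classifiers of gastric cancer
    molecular subtypes (CIN, GS, MSI, EBV) from DNA-level alterations only:
    somatic gene mutations, gene-level copy-number aberrations and
    methylation beta values. Provides pre-processing of gene-by-sample
    alteration matrices (boolean mutation collapse, probe-to-gene averaging,
    k-nearest-neighbour imputation, train-only min-max scaling), SMOTE class
    balancing, L1-penalised logistic node models with cross-validated
    penalty selection, one-step and multi-step cascade strategies with
    coherent composed subtype probabilities, one-vs-rest classification
    metrics, Kaplan-Meier/log-rank and multivariate Cox evaluation of
    clinical stratification, subtype alteration-rate statistics and
    subtype-specific marker discovery, plus a seeded multi-omics cohort
    simulator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
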