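Package: maldigo
Title: Gene Ontology Prediction from MALDI-TOF Mass Fingerprints of
    Knockout Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digitizes MALDI-TOF mass spectra of single-gene knockout
    strains into fixed-length binary fingerprint vectors and predicts Gene
    Ontology (GO) annotations from them. Implements per-GO-term Tanimoto
    positive-centroid scoring with a Mann-Whitney separation taxonomy,
    random-subspace tree ensembles (8 dimensions per tree, 500 trees,
    majority vote), and soft-margin RBF support vector machines with SMOTE
    class balancing, all evaluated by stratified 10-fold cross-validation
    with TPR/TNR/FPR/FNR and rank-based AUC. Assigns GO terms to strains of
    unknown genotype by averaging scores over the retained cross-validation
    models under a duplicate-consistency rule. Ships a synthetic
    knockout-library generator with planted, recoverable signature
    structure so the whole pipeline is testable end to end, plus Ward
    clustering with per-cluster GO fold enrichment for exploratory
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ape,
    kernlab,
    mzR,
    optparse,
    pROC,
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
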