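Package: clopisig
Title: Consensus SNP Signature Discovery for Clopidogrel Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control SNP analysis pipeline for discovering genetic
    signatures of clopidogrel resistance (high on-treatment platelet
    reactivity, PRU > 234) in diabetic peripheral artery disease cohorts.
    Provides a synthetic cohort generator with planted risk alleles,
    genotype/phenotype file input and output (TSV and minimal VCF),
    minor-allele-frequency and missingness quality control, allelic
    chi-square association with odds-ratio filtering, 100-fold bootstrapped
    three-learner consensus feature ranking (random forest, linear SVM,
    LASSO), AUC/accuracy feature-number sweeps across four classifiers,
    genotype-frequency comparisons, exact clinical statistics (Fisher,
    Mann-Whitney, two-proportion sample size), and protein-protein
    interaction subnetwork construction around the signature genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
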