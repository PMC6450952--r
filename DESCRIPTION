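Package: targetsafety
Title: Genetic Phenotypes of Drug Targets as Predictors of Clinical Side Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Retrospective pharmacovigilance analysis linking human-genetic
    phenotypes of drug-target genes to side effects observed in clinical
    trials. Drugs and their target genes are annotated with Mendelian and
    GWAS phenotypes at the MedDRA system-organ-class (SOC) level; each
    drug-organ pair is scored for genetic support (match, mismatch, or no
    information) and tested for enrichment of side effects with Fisher exact
    tests and Woolf odds-ratio intervals, per organ system and pooled.
    Includes structured permutation nulls (randomising gene-phenotype
    assignments or drug side-effect profiles), per-organ logistic and lasso
    regression models with a repeated cross-validation lambda-selection rule,
    a leakage-proof leave-one-target-set-out cross-validation of the
    predictive value of genetics (ROC AUC against a permuted-genetics null),
    and a synthetic-data generator emulating the statistical structure of
    the drug-target-phenotype dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
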