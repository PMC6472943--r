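Package: tamsig
Title: Tumor-Associated Macrophage Signature Derivation, Monocyte
    Classification, and Survival Analysis for Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for deriving and scoring
    tumor-associated macrophage (TAM) gene signatures from bulk RNA-seq
    data. Implements count-matrix preprocessing (CPM filtering, TMM and
    upper-quartile normalization, empirical-Bayes batch adjustment),
    empirical-Bayes moderated-t differential expression, a five-filter
    TAM signature cascade with a median-centered signature score, a
    blood-monocyte cancer classifier built on recursive feature
    elimination around a random forest with permutation-null
    significance testing, Kaplan-Meier and Cox proportional-hazards
    survival analysis with exhaustive optimal-cutpoint dichotomization,
    and CSF1/PAM50-style cohort stratification. A synthetic-data module
    generates every input class the pipeline consumes, with the
    statistical structure the analysis assumes, so the full workflow is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    randomForest,
    rlang,
    stats,
    survival,
    sva,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    caret,
    limma,
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
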