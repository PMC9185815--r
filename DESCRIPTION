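Package: pdacscreen
Title: Faecal Metagenomic Classifiers for Pancreatic Cancer Screening
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a species-level faecal metagenomic classification
    workflow for pancreatic ductal adenocarcinoma (PDAC): profile filtering,
    log10 pseudocount plus centred log-ratio normalization with frozen-parameter
    transfer to external cohorts, repeated cross-validated LASSO logistic
    regression ensembles (unconstrained and enrichment-constrained variants),
    fusion of classifier scores with the coded CA19-9 serum marker, calibration
    of a decision threshold to a target specificity, and cross-disease
    specificity evaluation on external cohorts. Includes rarefied Hill-number
    alpha diversity, Bray-Curtis beta diversity with strata-restricted
    PERMANOVA, a univariate Wilcoxon/generalised-fold-change screen, and a
    synthetic-cohort generator reproducing the statistical structure the
    analysis assumes (compositional log-normal abundances with structural
    zeros, enriched and depleted marker sets, cohort batch effects, a binary
    CA19-9 simulator).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    pROC,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Classification, Normalization
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
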