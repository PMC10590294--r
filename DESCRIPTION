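Package: TIMEscore
Title: Bootstrap Out-of-Bag Immune Biomarker Scoring for Immunotherapy Response
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates multidimensional tumor immune
    microenvironment (TIME) biomarkers that predict disease control under
    anti-PD-1 monotherapy from bulk RNA-seq. Turns a count matrix plus
    gene-set definitions into a panel of immune-signature features, builds
    candidate classifiers by forward feature selection with L2-regularized
    logistic regression over a regularization grid, scores their analytic
    variability on technical replicates (the 4*std metric), selects a final
    model under a dual clinical-performance/variability criterion, and
    produces a 0-100 ensemble score by bootstrap out-of-bag averaging with
    median thresholding. Includes sample quality-control filters, a full
    diagnostic-test evaluation suite (confusion-matrix metrics, likelihood
    ratios, diagnostic odds ratio, disease control rates, Fisher tests,
    relative risk, ROC/AUC, quartile analysis, predictor comparison,
    Kaplan-Meier/log-rank and Cox proportional hazards), an exact
    confusion-matrix reconstructor for published metric tables, and a
    synthetic-cohort generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    survival,
    fgsea,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
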