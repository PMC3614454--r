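Package: squamdx
Title: Tissue-of-Origin Classification of Head & Neck Versus Lung
    Squamous Cell Carcinoma with Bayesian Adaptive Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-class gene-expression similarity-score classifier that
    resolves head & neck squamous cell carcinoma (HNSCC) from lung squamous
    cell carcinoma (lung SCC) in formalin-fixed paraffin-embedded specimens,
    together with the statistical machinery used to validate such a
    diagnostic test: specimen-entry and microarray quality-control gating,
    quantile standardization to a frozen reference distribution, nested
    cross-validated model training with calibrated similarity scores that
    sum to 100, exact (Clopper-Pearson) diagnostic-accuracy statistics
    including the diagnostic odds ratio and ROC/AUC, a Bayesian adaptive
    group-sequential acceptance design with predictive-probability futility
    stopping, and inter-laboratory reproducibility analytics (concordance,
    Cohen's kappa, percent coefficient of variation). A synthetic-cohort
    generator with planted marker structure, site batch effects and
    quality-control artifacts makes every stage testable without
    proprietary assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
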