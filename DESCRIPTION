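Package: diffsen
Title: Predicting Transporter-Mediated Drug Resistance from Paired
    Drug-Sensitivity and Gene-Dependency Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates drug-sensitivity screens with gene-silencing
    (shRNA/CRISPR) viability screens across cancer cell line panels to
    predict drug resistance mediated by membrane transporters.  The core
    statistic, DiffSen, is the difference between cell viability under drug
    treatment and viability under silencing of the drug's primary target;
    a positive residual suggests the drug is being exported before it can
    act.  The package provides a harmonized input contract for sensitivity,
    silencing and feature matrices, a drug/target concordance filtering
    cascade, correlation-based feature selection with lasso, ridge and
    random-forest models tuned by five-fold cross-validation, within- and
    cross-dataset evaluation, Tanimoto fingerprint grouping of structurally
    similar drugs, rank aggregation of predictive features, enrichment
    tests against annotated transporter sets, and a synthetic cohort
    generator with planted transporter effects for end-to-end validation.
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
    igraph,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
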