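Package: methylmark
Title: Cancer-Type-Specific DNA Methylation Markers and Diagnostic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and evaluation of cancer-type-specific hyper-methylated
    CpG markers from Infinium 450K beta-value matrices across multiple tumor
    cohorts. Implements beta-value computation and probe exclusion rules,
    site- and region-level differential methylation with genome-feature
    enrichment, CpG island methylator phenotype (CIMP) calling by consensus
    and K-means clustering with survival comparison, cis/trans
    methylation-expression correlation screens, a progressive
    cohort-specificity filtering cascade, information-gain feature ranking
    with ridge-penalised logistic diagnostic models and ROC evaluation, and a
    synthetic multi-cohort data generator with planted ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    mclust,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    glmnet
Config/testthat/edition: 3
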