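Package: TCDtype
Title: T Cell Dysfunction Profiling, Consensus Subtyping and Prognostic Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds per-sample T cell dysfunction (TCD) profiles from bulk
    expression data by hypergeometric enrichment of fold-change-defined
    differentially expressed genes over four TCD state signatures (exhaustion,
    senescence, exclusion, dysfunction), derives severity-ordered tumour
    subtypes by consensus clustering (partitioning around medoids, Manhattan
    distance, delta-area model selection), and carries the subtypes through a
    full downstream analysis: signature scoring, differential miRNA and
    methylation-probe selection, univariate screening and multivariate Cox
    proportional-hazards risk modelling with high/low risk stratification,
    random-forest subtype classifiers with ROC/AUC evaluation, and an
    end-to-end reproducible pipeline. A synthetic cohort generator with
    planted subtype, miRNA, methylation and survival effects provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    survival,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
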