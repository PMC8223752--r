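Package: rascore
Title: Cross-Tissue Feature Selection and a Composite Expression Score for
    Rheumatoid Arthritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-tissue transcriptomic biomarker discovery in
    rheumatoid arthritis: multi-study preprocessing (quantile normalization,
    merging on common genes, empirical-Bayes batch adjustment, sex imputation),
    covariate-adjusted differential expression with moderated t-statistics,
    an iterative resampling feature-selection pipeline with co-directionality
    constraints across synovium and blood, independent-cohort per-gene
    validation, and a composite disease score defined as the difference of
    geometric means of up- and down-regulated panel genes, together with its
    clinical association statistics.  A synthetic compendium generator with a
    ground-truth record makes every stage testable without external data.
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
    limma,
    glmnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr
Config/testthat/edition: 3
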