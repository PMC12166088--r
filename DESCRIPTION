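Package: screenrec
Title: Drug-Response Recommendation from Probing Panels and Historical Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks an entire drug library for a new patient-derived cell
    culture from a small probing panel screened on that culture plus a
    historical cell-line by drug response matrix. Implements matrix
    ingestion, pruning and activity transforms for pIC50, inverse
    log2-fold-change and viability screens; zero-fill and boosted-stump
    (transformational machine learning) imputation; correlation-diversity
    and random probing-panel selection; a random-forest recommender with
    per-cell-line feature importances; top-n overlap and top-k hit-rate
    evaluation; repeated hold-out and leave-one-out experiment protocols;
    and a low-rank synthetic screen generator with known ground truth.
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
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
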