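Package: icuhybrid
Title: Hybrid Semantic-Clustering and Boosted-Tree Models of ICU Mortality Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Interpretable risk-of-death modelling for mechanically
    ventilated ICU patients. Clinical features are grouped by the semantics
    of per-feature textual descriptions (TF-IDF vectorisation followed by
    fuzzy C-means soft clustering with thresholded multi-membership); each
    cluster trains a weak gradient-boosted-tree classifier whose out-of-fold
    predictions feed a strong meta-classifier, yielding a hierarchically
    structured ensemble. Includes cohort construction from raw bedside time
    series (ventilation onset, observation-window aggregation,
    criteria-based flags, race-free CKD-EPI eGFR), hierarchical gain-based
    feature importance, exact and permutation-sampled Shapley explanations
    at the cluster level, evaluation and model-comparison utilities, and
    seeded synthetic-data generators for corpora, patient cohorts and
    time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    e1071,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
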