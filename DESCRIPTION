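Package: crowdihc
Title: Crowdsourced Immunohistochemistry Scoring and Prognostic Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing crowdsourced scoring of immunohistochemistry
    tissue-microarray images. Simulates heterogeneous-reliability crowds scoring
    tumor-core sub-images, estimates per-user reliability with an iterative
    user-performance-score algorithm, aggregates crowd answers into pseudo-Allred
    estrogen-receptor scores by (weighted) ordinal medians, evaluates accuracy
    against a reference scorer (ROC/AUC, sensitivity, specificity, Spearman
    correlation), and validates prognostic value with Kaplan-Meier curves and a
    Cox model in which the estrogen-receptor log hazard ratio varies linearly
    with follow-up time, with chained-equation imputation of missing stage and
    grade pooled by Rubin's rules. Includes the image preparation steps (color
    negation, saturation/hue transform, tiling) applied before crowd scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    MASS,
    nnet,
    data.table,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
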