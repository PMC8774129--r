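Package: ncscreen
Title: Noncoding RNA Biomarker Panels for Multi-Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stability-selection ranking of noncoding RNA biomarkers from TPM
    expression matrices, fixed-architecture feed-forward neural-network
    classifiers for cancer-vs-normal and multi-cancer discrimination,
    accumulated-biomarker ROC/AUC evaluation, cross-cohort validation by
    marker intersection, baseline comparison against random forests and
    decision trees, and a Kruskal-Wallis turning-point procedure that fixes
    a stable biomarker panel size. Includes a synthetic TPM cohort generator
    with planted informative markers so the whole pipeline is testable
    without access to consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    randomForest,
    rpart,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
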