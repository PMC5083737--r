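Package: karyoclass
Title: Karyometric Classification of Pancreatic Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative histopathology (karyometry) pipeline for
    classifying pancreatic tissues as chronic pancreatitis, intraductal
    papillary mucinous neoplasm, or pancreatic carcinoma from nuclear
    shape and chromatin-texture features. Provides nucleus segmentation
    and gray-level run-length texture extraction, a penalized multinomial
    logistic regression engine (lasso and group-lasso) with
    cross-validated regularization-path tuning, a classification-certainty
    score, tissue- and nuclear-level analyses with repeated train/test
    split evaluation, and a seeded synthetic-cohort generator for
    end-to-end testing when original images are unavailable.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    withr,
    EBImage,
    pROC,
    ggplot2,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
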