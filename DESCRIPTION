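Package: xconsist
Title: Consistency of Post-Hoc Model Explanations Under Class Imbalance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative framework for measuring how stable post-hoc
    explanations (LIME local surrogates, Shapley values, partial dependence
    profiles) remain when binary classifiers are trained under varying
    degrees of class imbalance. Provides a seeded synthetic clinical cohort
    generator with a logistic risk model, the data-manipulation protocol
    (stratified splitting, fixed-size imbalance subsets, random-undersampling
    balanced reference, balanced test sampling), first-principles
    implementations of LIME, exact and permutation-sampled Shapley values and
    partial dependence curves, union-normalized top-k Jaccard and Rank
    Agreement consistency metrics with class-wise aggregation, and the
    evaluation machinery (ROC-AUC, Youden's J operating point, bootstrap
    performance distributions, Mann-Whitney U and Wilcoxon signed-rank
    tests), orchestrated by a config-driven experiment sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    ranger,
    xgboost,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
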