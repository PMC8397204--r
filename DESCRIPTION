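Package: coarctscore
Title: Likelihood-Ratio Scoring for Prenatal Prediction of Coarctation of
    the Aorta
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a likelihood-ratio multiparameter scoring system
    that estimates the post-test probability of postnatal coarctation of
    the aorta (CoAo) in fetuses referred for cardiac asymmetry with right
    dominance.  The score combines gestational age at diagnosis,
    ascending-aorta and aortic-isthmus (three-vessels-and-trachea view)
    z-scores and the pulmonary-to-aortic valve diameter ratio through
    positive and negative likelihood ratios applied to fixed pre-test
    odds.  The package also provides the full validation machinery
    (empirical ROC curves, Mann-Whitney AUC with DeLong confidence
    intervals, Youden and maximum-sensitivity/-specificity operating
    points, Wilson confidence intervals for diagnostic proportions,
    onset-subgroup and probability-band analyses, group comparisons), a
    pluggable polynomial z-score reference framework, alternative
    published rule-based CoAo predictors for head-to-head benchmarking,
    and a seeded synthetic cohort generator so every analysis stage runs
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
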