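Package: texnac
Title: Texture and Kinetic Analysis of Dynamic Breast MRI for
    Predicting Non-Response to Neoadjuvant Chemotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for pre-treatment dynamic contrast-enhanced
    breast MRI analysis aimed at predicting pathological non-response to
    neoadjuvant chemotherapy. Provides synthetic dynamic-series phantom
    and cohort generation with ground-truth lesion masks; subtraction
    imaging and semi-quantitative kinetic parameters (amplitude, wash-in,
    wash-out); automated lesion segmentation by k-means clustering of
    kinetic maps with morphological cleanup; grey-level co-occurrence and
    run-length matrix texture features; group-comparison and
    mono-parametric discrimination statistics (Wilcoxon rank-sum,
    D'Agostino-Pearson normality, mid-P Fisher exact test, empirical ROC
    with Youden cut-offs and DeLong AUC comparison); and multi-parametric
    classification (logistic regression and an L1-distance k-means
    classifier) with leave-one-out cross-validation and exhaustive
    feature-subset search.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
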