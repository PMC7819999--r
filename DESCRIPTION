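Package: sarclass
Title: DNA Methylation Array Classification of Soft Tissue and Bone Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end DNA methylation array classification of sarcoma
    cohorts: per-sample normalization of two-channel intensities
    (background and dye-bias correction), cohort-level batch adjustment,
    beta-value computation, sample and probe quality filtering,
    unsupervised embedding (t-SNE, hierarchical clustering), a
    class-balanced Random Forest classifier with vote-fraction raw
    scores, probability calibration by L2-penalized multinomial logistic
    regression tuned with a Youden-index resampling criterion at a fixed
    0.9 reporting threshold, methylation-class-family score aggregation,
    nested cross-validation metrics (misclassification rate, Hand-Till
    multi-class AUC, Brier score), and copy-number profiles from
    combined probe intensities with genomic binning and change-point
    segmentation. Includes a synthetic-cohort generator with
    class-specific beta archetypes, tumour-purity mixing, batch effects,
    control probes and injected copy-number events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    matrixStats,
    limma,
    randomForest,
    Rtsne,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
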