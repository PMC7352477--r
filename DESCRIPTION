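Package: tepscore
Title: Swarm-Optimized Classification of Tumor-Educated Platelet RNA Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spliced-RNA profiles of tumor-educated
    platelets (TEPs): per-transcript ANOVA differential expression with
    Benjamini-Hochberg FDR control, particle-swarm optimization of the four
    biomarker-panel selection hyperparameters (library-size correlation floor,
    FDR threshold, label-correlation threshold, ranked-transcript count), a
    support-vector-machine TEP-score classifier with Platt-calibrated
    probabilities and a strict train/evaluation/validation locking discipline,
    permutation (shuffled-label) and split-robustness controls, unsupervised
    hierarchical clustering with a cluster-group association test, and
    transcript-signature overlap analysis. Ships a negative-binomial synthetic
    cohort generator with planted ground truth so the whole pipeline is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    e1071,
    jsonlite,
    yaml,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
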