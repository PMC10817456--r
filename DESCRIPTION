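Package: tmseegdx
Title: Resting-State and TMS-Evoked EEG Biomarkers for Depression Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for discriminating major
    depressive disorder from healthy controls using frontal resting-state EEG
    and single-pulse TMS-evoked EEG. Implements band power, weighted phase lag
    index (wPLI) connectivity, phase-amplitude coupling modulation index (MI),
    four-modality feature construction (resting, pre-stimulus, post-stimulus,
    and post-minus-pre difference), Mann-Whitney feature screening, nested
    double cross-validation of nine classifiers with vertically averaged ROC
    curves, permutation feature importance with cross-model intersection, and
    age-adjusted ANCOVA / Spearman correlation follow-up statistics. Includes
    a synthetic two-group cohort generator that plants controllable group
    effects in the signal domain so every stage is testable without patient
    data, plus BrainVision and EDF readers for real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    e1071,
    class,
    rpart,
    randomForest,
    ranger,
    xgboost,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
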