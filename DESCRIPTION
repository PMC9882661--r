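Package: pinnBP
Title: Physics-Informed Neural Networks for Cuffless Blood Pressure
    Estimation from Bioimpedance Waveforms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for translating beat-segmented wearable bioimpedance
    waveforms into continuous blood pressure with a physics-informed
    neural network (PINN). The physics prior is a per-beat first-order
    Taylor expansion of the feature-to-pressure map, enforced as an
    unsupervised residual loss over all consecutive beats, which lets a
    small 1D-CNN regressor train accurately from a minimal set of
    reference cuff labels (roughly one label per mmHg of pressure range).
    Includes beat segmentation, fiducial-point and feature extraction,
    a synthetic beat generator with known hemodynamic couplings for
    validation, label-budget split protocols, training with the
    supervised-loss stopping rule, Bland-Altman/AAMI-style evaluation,
    and gradient-interpretation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    pracma,
    readr,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Regression, TimeCourse, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'signal-features.R'
    'simulate.R'
    'pinn-model.R'
    'pinn-loss.R'
    'training.R'
    'evaluation.R'
    'io.R'
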