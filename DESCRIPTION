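Package: painAU
Title: Privacy-Preserving Pain Detection from 3D Face Landmark Sequences
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects facial action units (AUs) and estimates their intensities
    from anonymized 3D face landmark sequences with a lightweight
    fully-connected network, then classifies pain versus non-pain expression
    from AU time series with a Transformer encoder (and an LSTM baseline).
    Includes Procrustes landmark normalization, landmark-space data
    augmentation for rare AUs, an HDF5 dataset container, a forward simulator
    that renders landmark sequences from ground-truth AU activation
    timecourses, and a subject-independent cross-validation and metrics
    harness (per-AU F1, intensity RMSE/MAE, pooled confusion matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Classification, Regression, TimeCourse, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'landmarks-io.R'
    'augment.R'
    'nnet-dense.R'
    'au-models.R'
    'transformer.R'
    'lstm.R'
    'pain-models.R'
    'simulate.R'
    'evaluate.R'
    'checkpoint.R'
    'config.R'
    'reference.R'
    'painAU-package.R'
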