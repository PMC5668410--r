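Package: coordFrames
Title: Coordinate-Frame Identification from Multi-Voxel Activity Patterns
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the coordinate frame (extrinsic, joint-like, or
    muscle-like) embedded in the multi-voxel activity pattern of a cortical
    region during an isometric wrist aiming task performed under two forearm
    postures. Provides cosine-tuning fits and preferred-direction shift
    estimates with circular summary statistics for intramuscular EMG data, a
    linear direction classifier with within- and across-posture
    generalization profiles and an asymmetry index, and a
    rotation-parameterized common decoder whose prediction-error curve over
    candidate rotation angles yields the coordinate index of a region.
    Includes a synthetic population-code generator (cosine-tuned units whose
    preferred directions rotate by a known angle under posture change,
    linearly mixed into voxels) and the signal-conditioning steps from raw
    run time series to trial patterns, so the full pipeline is testable
    without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
biocViews: Software, StatisticalMethod, Classification, Regression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
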