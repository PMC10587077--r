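Package: bmilfp
Title: Spectral Decoding and Directed Connectivity of Field Potentials
    During Brain-Machine Interface Control
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multichannel local field potentials (LFP)
    recorded simultaneously from primary motor cortex (M1), dorsolateral
    prefrontal cortex (DLPFC) and the caudate nucleus (Cd) while a subject
    performs a center-out task under brain-machine interface (BMI) or manual
    control. Implements signal conditioning and common median referencing,
    Welch band-power feature extraction in five canonical frequency bands,
    task-type and target-direction discriminant classification with
    permutation-calibrated chance, and baseline-normalized directed Granger
    causality networks with an artifact-calibrated null. A closed-loop
    velocity Kalman-filter decoder with SmoothBatch adaptation and a
    center-out task engine double as a synthetic multi-day study generator
    with known ground truth, so every stage of the pipeline can be validated
    without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    matrixStats,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    MASS,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Electrophysiology, TimeCourse, Classification, Network
RoxygenNote: 7.3.3
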