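Package: anchorsearch
Title: Simulation and Multivariate Analysis of Context-Guided Visual Search Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing combined fMRI and eye-tracking
    experiments on context-guided visual search, in which a target object is
    found via a contextually associated "anchor" object and the target-anchor
    pairing reverses across scene contexts. Provides a factorial trial
    generator, a synthetic voxel-pattern and gaze generator with known ground
    truth, run-wise GLM estimation with a canonical double-gamma HRF,
    localizer-driven voxel selection with nested sub-ROIs, linear decoding
    (leave-one-run-out and cross-scene generalisation) scored by a z-scored
    distance-to-bound classifier-information statistic, participant bootstrap
    tests, threshold-free cluster enhancement with sign-flip max-statistic
    correction, sphere searchlight mapping, and first-fixation guidance and
    signal-detection analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
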