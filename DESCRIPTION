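Package: gaitsense
Title: Smartphone Six-Minute Walk Test Gait Analysis and Fall-Risk
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processes smartphone inertial sensor recordings from a
    six-minute walk test (6MWT) into a fall-risk classification for lower
    limb amputees. Provides zero-lag Butterworth preprocessing, rule-based
    and trainable per-frame foot-strike detection with adaptive
    locking-period post-processing (duplicate collapse and missed-step
    insertion), a 62-feature-per-step registry (temporal, descriptive and
    spectral gait descriptors including the symmetry index and the ratio
    of even-to-odd harmonic power), aggregation to 248 features per
    participant, correlation-based feature selection and random-forest
    leave-one-out cross-validated classification. A synthetic 6MWT gait
    generator with known ground-truth foot strikes makes the full pipeline
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
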