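Package: eegleak
Title: Band-Energy EEG Classification with Leakage-Aware Cross-Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for epoch-based classification of multichannel EEG by
    rhythm band energies and time-domain statistics, together with the two
    resampling schemes whose disagreement exposes epoch leakage: pooled
    stratified k-fold cross-validation over epochs versus
    leave-one-subject-per-class-out cross-validation. Includes a synthetic
    EEG cohort generator with independently controllable class-level
    spectral effects (EEG slowing) and subject-level spectral fingerprints,
    a Butterworth preprocessing chain (artifact-interval removal,
    decimation, band-pass), overlapping epoch extraction, a five-band
    energy + mean/variance/IQR feature table, six classical classifiers,
    EDF input/output, and an end-to-end experiment runner with a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    rpart,
    randomForest,
    nnet,
    e1071,
    class,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
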