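Package: gaitwave
Title: Gait-Phase-Locked EEG Amplitude Analysis with Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mobile EEG recorded during walking:
    band-specific Butterworth pre-filtering with 50 Hz notch, fastICA
    decomposition with rule-based artifact-component removal, gait-cycle
    segmentation from a thigh-mounted inertial sensor, per-cycle amplitude
    and time normalization into electrode-by-gait-phase matrices, and
    statistical non-parametric mapping (SnPM) over the gait cycle using a
    two-way mixed-design permutation ANOVA with max-statistic thresholds,
    suprathreshold-cluster p-values and Bonferroni-corrected post hoc
    contrasts. Includes a synthetic-data module that generates synchronized
    EEG and IMU walking recordings with known gait events, artifact sources
    and injectable group-by-condition effects, so every stage is testable
    without access to laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
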