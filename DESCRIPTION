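Package: eemquench
Title: Quenching-Based Reliability Diagnostics for EEM-PARAFAC Water Monitoring
Version: 0.1.0
Authors@R: person("Greywater", "Monitoring Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for excitation-emission matrix (EEM) fluorescence analysis
    built around paired original/quencher-dosed measurements. Provides EEM
    input/output and preprocessing (inner filter effect correction,
    Rayleigh/Raman scatter removal, median filtering), nonnegative PARAFAC by
    hierarchical alternating least squares with split-half component-number
    selection and Tucker congruence matching, the apparent F0/F quenching-ratio
    indicator per PARAFAC component, F0/F-driven clustering with per-cluster
    PARAFAC models, a train/predict monitoring workflow with z-score-trimmed
    reference ranges for outlier flagging, classical fluorescence indices
    (HIX, BIX, AQY, reconstruction error), and a physics-based synthetic EEM
    simulator with Stern-Volmer quenching for validation without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
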