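Package: fingerqc
Title: Quantitative Chromatographic Fingerprint Quality-Consistency Analysis
Version: 0.1.0
Authors@R:
    person("fingerqc", "developers", email = "fingerqc@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating the batch-to-batch quality consistency of
    multi-component herbal preparations from multi-wavelength HPLC
    fingerprints. Implements the systematic quantitative fingerprint method
    (SQFM): cosine-based qualitative similarity, projection-based
    quantitative similarity, the fingerprint leveling coefficient, an
    eight-grade quality classification, and root-mean-square integration
    across detection wavelengths. Also provides common-peak matching across
    batches, calibration-curve quantitation of marker compounds with
    LOD/LOQ, off-line DPPH radical-scavenging IC50 estimation, on-line
    (post-column) antioxidant activity-fingerprint peak detection, PCA
    outlier screening, NIPALS PLS and OPLS fingerprint-efficacy regression
    with cross-validation and jack-knife coefficient intervals, and a
    synthetic fingerprint generator with known ground truth for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
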