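Package: echodim
Title: Keypoint-Based Left-Ventricular Dimension Measurement and
    Multi-Expert Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating automated echocardiographic linear
    measurements of the left ventricle against a multi-expert consensus.
    Implements the parasternal long-axis keypoint measurement geometry
    (septal thickness, internal diameter, posterior-wall thickness from
    four landmarks), Gaussian-heatmap keypoint encoding and peak decoding,
    centre-crop and augmentation conventions for heatmap regression,
    construction of a median-of-experts consensus reference standard,
    agreement statistics (bias, precision SD, absolute-deviation
    quantiles, ICC(2,1), variance-ratio F test, Wilcoxon signed-rank),
    and the decomposition of keypoint error into components along and
    perpendicular to the consensus measurement line.  A synthetic
    phantom and simulated-rater generator reproduces the structure of a
    multi-reader validation study so the whole pipeline is testable
    without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
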