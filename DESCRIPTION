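Package: nirsleep
Title: Sleep-Stage-Stratified Analysis of Infant fNIRS Auditory Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing block-design functional near-infrared
    spectroscopy (fNIRS) recordings from naturally sleeping infants,
    stratified by behaviourally coded sleep stage. Provides a synthetic-data
    generator for dual-wavelength intensity recordings with stimulus
    schedules, sleep-stage timelines and behavioural coding sheets; channel
    quality control (scalp coupling index, peak spectral power); motion
    artifact detection and spline/wavelet correction; optical-density and
    modified Beer-Lambert chromophore conversion; trial-locked block
    averaging; epoch-based sleep-stage scoring with codability exclusion and
    inter-rater ICC; rules allocating trials to quiet-sleep and active-sleep
    groups per analysis; and a statistics kernel (Welch and pooled t-tests,
    Cohen's d, IQR outlier filtering, Benjamini-Hochberg FDR, permutation
    tests and bootstrap confidence intervals) driving ROI-based and
    channel-wise activation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'paradigms.R'
    'staging.R'
    'synthetic.R'
    'preprocess.R'
    'allocation.R'
    'statistics.R'
    'analysis.R'
    'pipeline.R'
    'io.R'
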