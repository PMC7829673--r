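Package: fnirsuite
Title: Resting-State and Task fNIRS Signal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis suite for functional near-infrared spectroscopy
    (fNIRS) hemodynamic time series covering the full pipeline from data
    preparation to group inference: SNIRF and plain-text input, modified
    Beer-Lambert conversion of optical intensity to hemoglobin concentration
    changes, composable preprocessing (trimming, polynomial detrending, CBSI
    and TDDR motion correction, IIR/FIR/FFT filtering, short-channel noise
    regression, resampling, user plugins), individual-level resting-state
    indices (functional connectivity, ALFF/fALFF with z-standardization,
    network thresholding and connectome export), channelwise GLM activation
    analysis with the canonical double-gamma HRF, and group-level channelwise
    statistics with FDR and Bonferroni correction within masks. A synthetic
    recording generator with known ground truth supports validation of every
    stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    rhdf5,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'methods-NirsRecording.R'
    'methods-containers.R'
    'io-snirf.R'
    'io-text.R'
    'mbll.R'
    'filters.R'
    'preprocess.R'
    'pipeline-spec.R'
    'resting.R'
    'taskglm.R'
    'groupstats.R'
    'qc.R'
    'synthetic.R'
    'batch.R'
    'fnirsuite-package.R'
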