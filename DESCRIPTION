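Package: calwhisk
Title: Awake Two-Photon Calcium Imaging Analysis with Whisking-State
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of awake two-photon calcium imaging
    recordings with simultaneous whisker videography. Covers rigid
    full-frame registration on an anatomical channel, ROI trace
    extraction with neuropil correction, percentile-based delta-F/F and
    noise-band estimation, calcium-transient detection, whisking-epoch
    segmentation from behavior-video intensity, whisking-responsiveness
    classification, transient kinetics (decay and half-decay times), and
    state-restricted pairwise correlations with circular-shift surrogate
    nulls. Includes a synthetic-data generator with full ground truth
    (event times, state sequence, applied motion) so every stage of the
    pipeline can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
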