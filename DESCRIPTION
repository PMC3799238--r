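Package: iedflow
Title: Peri-Event Analysis of Interictal Epileptiform Discharges in
    Microelectrode Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-unit firing and local field
    potential (LFP) dynamics around interictal epileptiform discharges
    (IDs): threshold-based ID detection and sharpest-peak alignment,
    peri-event rasters and time histograms with firing-rate modulation
    classification over baseline/pre-ID/ID/post-ID windows, Morlet
    wavelet time-frequency maps with baseline Z-score normalisation,
    and two surrogate-based spike-synchrony tests (normal-jitter
    cross-correlogram bands and uniform-dither coincidence thresholds).
    Includes a ground-truth-labelled synthetic-data generator (1/f LFP
    with embedded discharge waveforms, inhomogeneous Poisson spike
    trains, injected correlated pairs) and an end-to-end reproducible
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    nortest,
    signal,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
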