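Package: stwiring
Title: Space-Time Wiring Models of Direction Selectivity in Starburst
    Amacrine Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for the bipolar-to-starburst amacrine
    cell (SAC) circuit of the mammalian retina. Provides a center-surround
    receptive-field model of bipolar cell responses to moving bars and
    flashes with adaptation and glutamate-sensor filtering, a branched-cable
    compartmental SAC model with N-type calcium channels and a dendritic
    calcium pool, an elitist evolutionary algorithm that optimizes
    presynaptic receptive fields and postsynaptic biophysics for directional
    tuning, receptive-field estimation from multi-velocity motion waveforms,
    and a glutamate-imaging analysis pipeline (pixel selection, ROI
    segmentation, functional clustering, filtered back-projection
    receptive-field mapping). Synthetic-data generators emulate the
    experimental recordings so every stage can be exercised and tested
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    minpack.lm,
    Rcpp,
    signal,
    stats
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
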