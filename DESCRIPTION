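Package: grfpress
Title: Ground Reaction Force Estimation from Plantar Pressure During Graded Running
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating time-continuous vertical and
    anterior-posterior ground reaction forces (GRFs) from five-region
    plantar-pressure insole signals during treadmill running at different
    speeds and slopes.  Includes a synthetic cohort simulator with known
    ground truth (dual-rate insole and force-plate streams, synchronization
    jumps, configurable pressure-to-force mapping), a preprocessing chain
    (gravity-frame rotation, zero-phase Butterworth filtering,
    cross-correlation synchronization, stance segmentation, five-region
    summation, 101-node time normalization), two estimator families
    (per-condition and pooled least-squares linear models, and a
    bidirectional LSTM sequence-regression network trained with Adam,
    implemented natively), leave-one-subject-out validation with
    subject-specific fine-tuning, and an evaluation stack: RMSE, Pearson
    correlation, range-normalized time-continuous percent error, and
    one-dimensional statistical parametric mapping with random-field-theory
    critical thresholds and suprathreshold clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    rhdf5,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
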