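Package: allodecode
Title: Simulation and Multivariate Decoding of Allocentric Direction
    Signals in fMRI Region-of-Interest Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, fully simulated multivoxel pattern analysis
    (MVPA) pipeline for allocentric boundary and goal direction decoding
    in a virtual spatial-navigation task. Builds the balanced 24-path,
    96-trial-per-run experimental design with orthogonal allocentric
    boundary and goal direction factors; simulates region-of-interest
    BOLD time series with planted direction-specific multivoxel patterns,
    motion-coupled nuisance and AR(1) noise; removes nuisance signal with
    a 24-regressor motion confound model and a 128-s cosine high-pass
    filter; estimates single-trial response amplitudes with an additive
    per-trial general linear model; averages trials across runs into
    condition-balanced samples; classifies direction with a nested
    cross-validated linear support vector classifier; and performs
    group-level inference with BCa bootstrap confidence intervals and a
    shifted-to-chance Monte Carlo significance test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    utils,
    withr,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
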