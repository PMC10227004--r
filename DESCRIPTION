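Package: cardiomap
Title: Cardiac Optical Mapping Analysis and Synthetic Tissue Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement chain for panoramic cardiac optical mapping
    recordings: per-pixel activation times from the maximum upstroke
    derivative, action potential duration at 80% repolarization (APD80),
    single-vector conduction velocity, isochrone maps, APD restitution
    curves and slopes, and nonparametric group statistics
    (Kruskal-Wallis, Dunn's post hoc, trend over pacing cycle length)
    together with Teichholz ejection fraction. Includes a synthetic
    voltage-movie generator (closed-form plane waves with analytic
    ground truth, and a two-variable excitable-medium
    reaction-diffusion simulator) matching a 128 x 128 pixel, 30 x 30
    mm, 2-ms-frame acquisition with constant pacing at cycle lengths
    400-150 ms, so every stage of the pipeline is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    signal,
    minpack.lm,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
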