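Package: tracksearch
Title: Single-Molecule Tracking Analysis of the DNA Target Search in
    Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how bacterial DNA-binding proteins search
    for their chromosomal targets from photoactivated single-molecule
    tracking data. Includes a Monte Carlo simulator of confined Brownian
    motion in spherocylindrical cell volumes with two-state (bound/free)
    interconversion, sub-frame motion blur, photobleaching and
    localization noise; synthetic movie rendering with band-pass spot
    detection and elliptical Gaussian localization; minimum-distance
    track linking with gap memory; apparent diffusion coefficient (D*)
    statistics with analytic sampling distributions, two-species mixture
    fitting and cell-level bootstraps; simulation-matching inference of
    unbiased diffusion coefficients and of the transiently DNA-bound
    time fraction; three-state partitioning of protein activity;
    mass-scaling power laws; chromosome occupancy accounting; and
    kymograph analysis of pole-to-pole protein oscillations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    pracma,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
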