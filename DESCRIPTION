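Package: surfstab
Title: Surface-Based Dynamic Functional Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes per-vertex functional stability of resting-state BOLD
    signals on triangulated cortical surfaces, defined as the Kendall
    concordance of sliding-window functional-connectivity maps across
    windows. Includes lightweight surface geometry (icospheres, vertex
    areas, adjacency, FWHM-calibrated diffusion smoothing), subject-level
    preprocessing (initial-volume discard, Friston-24 motion regression,
    band-pass filtering, motion quality control), group-level inference
    (vertex-wise GLM, cluster formation with an areal extent threshold,
    permutation cluster p-values with Benjamini-Hochberg control),
    clinical-covariate correlation, a window/step/smoothing
    reproducibility protocol, and a fully synthetic two-group cohort
    generator with known stationary and temporally modulated connectivity
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite,
    data.table,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
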