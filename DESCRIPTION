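Package: trigsar
Title: Worst-Case Local SAR for Parallel-Transmit MRI by Trigonometric
    Maximization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Determines the exact worst-case 10g-averaged local specific
    absorption rate (SAR) for multi-channel MRI transmit arrays when the
    per-channel amplitudes are known but the phases are not. Local SAR in a
    voxel is a Hermitian quadratic form in the complex channel drives; as a
    function of the drive phases it is a linear combination of cosines, and
    the phase set attaining its maximum is found by a fixed-point coordinate
    scheme with two-argument arctangent updates. The package builds voxelwise
    Q-matrices from per-channel electric-field maps and tissue properties,
    performs 10g cubical averaging, compresses Q-matrix sets to virtual
    observation points with a bounded overestimation guarantee, and provides
    the classical comparator estimators (total-power eigenvalue bound,
    reference-phases estimate with calibrated correction factors, and
    eigenvector-based lower/upper bounds), together with synthetic phantom
    and drive generators and brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rhdf5,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    methods,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
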