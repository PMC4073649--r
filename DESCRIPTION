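Package: megharmonics
Title: Empirical Spatial-Distortion Bounds for MEG Source Reconstructions
    via Spherical-Harmonic Cortical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents a cortical surface as a nested family of
    spherical-harmonic (weighted Fourier series) models of increasing
    harmonic order, inverts MEG sensor data onto every member of the family
    under minimum-norm (MNM) or multiple-sparse-priors (MSP) covariance
    assumptions within a parametric empirical Bayes framework, and uses
    variational free energy (log model evidence) comparisons to find the
    highest distinguishable harmonic (HDH): the simplest anatomy still
    distinguishable from the full one.  The 95th-percentile vertex
    displacement of the HDH surface is an empirical upper bound on the
    spatial distortion of the functional estimate, obtained without any
    functional ground truth.  Includes a synthetic-anatomy generator
    (band-limited two-hemisphere cortices, helmet-like sensor arrays), an
    analytic spherical-conductor forward model, and a simulation harness
    reproducing patch-source, point-source and noise-only scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    tidyr,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
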