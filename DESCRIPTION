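Package: maupsi
Title: Multiscale Zonation Ensembles and Simulation Intervals for the
    Modifiable Areal Unit Problem
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and managing the modifiable areal unit
    problem (MAUP) in the estimation of associations from spatially
    aggregated data.  Builds ensembles of contiguity-constrained zonations
    of a building-block geography at many population scales, fits
    negative-binomial rate, weighted-Gaussian, or Poisson association
    models at every scale-by-zonation combination, fits log-log scaling
    curves to the resulting parameter estimates, and constructs
    minimal-level simulation intervals (SIs) for the true effect via a
    nested-simulation bound search.  Also provides the univariate
    multi-zonation overlay statistic (repeat-appearance probabilities of
    high-rate areas) and a grid-shift analysis for modifiable minimal
    units, together with synthetic lattice scenario generators with known
    data-generating parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
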