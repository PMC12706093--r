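Package: svfusion
Title: Morphometric Classification and Kinetic Modelling of Synaptic Vesicle Fusion Intermediates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of synaptic vesicle (SV)
    fusion intermediates captured by timed in situ cryo-electron tomography.
    Provides a seeded generator of synthetic membrane-profile images and
    synapse-population tables, morphometric measurements of membrane
    rearrangements (including a grayscale line-scan gap statistic and
    least-squares circle fits), a rule-based classifier of seven fusion
    states, population census statistics with exact contingency-table tests,
    a continuous-time Markov state model of fusion kinetics fitted from
    single-snapshot state counts, and a reduced-fidelity coarse-grained
    Brownian-dynamics simulator of SV docking at the active zone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
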