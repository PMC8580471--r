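Package: fibrinbd
Title: Mesoscopic Brownian Dynamics of Fibrin Protofibril Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained Brownian dynamics of fibrin protofibrils, modelled
    as 22-node bead chains interacting through five harmonic potentials
    (stretch, bend, torsion, inter-fibre aggregation and short-range
    repulsion) plus thermal noise in a periodic box. Provides seeded network
    generation at a given fibrinogen concentration, an overdamped Euler/RK4
    split integrator with xorwow/Box-Muller noise, a virtual uniaxial stretch
    test with engineering stress from the smoothed energy gradient and
    least-squares elastic modulus, conformation observables (tortuosity,
    orientation statistics, stretched-fibre fraction, aggregation-bond
    survival) and SEM-like projection imaging with Sobel/Gaussian filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
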