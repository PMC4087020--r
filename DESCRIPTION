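Package: micellemix
Title: Mixed-Micelle Thermodynamics and Coarse-Grained Self-Assembly Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Regular-solution-theory analysis of binary mixed micellisation
    (Clint ideal critical micelle concentration, Rubingh micellar composition
    and interaction parameter), extraction of critical micelle concentrations
    from raw fluorimetric titration and conductivity curves (Boltzmann sigmoid
    and segmented-line breakpoint fitting with counterion-binding assessment),
    and analysis of coarse-grained surfactant self-assembly trajectories:
    closest-bead cluster detection under periodic boundary conditions,
    aggregate size and composition statistics with block averaging,
    gyration-tensor shape anisotropy, counterion condensation bookkeeping,
    radial bead distributions and head-to-tail orientation angles. Includes
    ground-truthed synthetic data generators (measurement curves, constructed
    micelle configurations, and a toy Langevin aggregation simulator) so every
    analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
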