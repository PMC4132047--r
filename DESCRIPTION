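Package: silkfric
Title: Viscous Friction Between the Crystalline and Amorphous Phases of Spider Silk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the interfacial viscous friction coefficient between
    beta-sheet crystallites and the disordered matrix of spider dragline silk from
    force-probe pulling data. Builds idealized crystal/amorphous composite structures,
    computes solvent-accessible contact areas (Shrake-Rupley), emulates constant-velocity
    spring-pulling experiments with an overdamped Langevin model, extracts per-velocity
    peak friction forces with water-drag subtraction, fits a Fokker-Planck washboard
    bond-friction model to the force-velocity data, extrapolates to the viscous-limit
    coefficient of viscosity, and feeds the result into a small explicit-dynamics
    slider model of a crystalline block sliding on a viscoelastic plate through a
    Newtonian lubrication film.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    bio3d
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
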