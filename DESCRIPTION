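Package: ecsmc
Title: Effective Charge Surface Free Energies for Water and Aqueous Electrolytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes accurate free energies of water and aqueous electrolyte
    solutions from non-polarizable rigid force fields using a dual charge
    surface: the potential energy surface (PES) charges sample configurations,
    while a scaled effective charge surface (ECS) evaluates absolute excess
    chemical potentials. Includes a compact continuous fractional component
    Monte Carlo (CFCMC) engine in the NPT ensemble (Lennard-Jones plus Ewald
    electrostatics, Wang-Landau biased lambda sampling, Widom insertion
    cross-checks) and a thermodynamic post-processing layer that converts
    excess chemical potentials into free-energy corrections, water activities,
    hydration free energies, and vapor-liquid coexistence properties via a
    Peng-Robinson fugacity-consistent saturation-pressure solver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
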