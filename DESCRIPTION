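Package: shellmd
Title: Extended-Lagrangian Core-Shell Polarizable Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Molecular dynamics with the core-shell (Drude) polarizable
    force-field model in which shells are propagated as fictitious dynamical
    variables adiabatically decoupled from the nuclei by dedicated Nose-Hoover
    chain thermostats acting on relative core-shell coordinates. Bundles a
    low-point-charge polarizable silica force field (p-MZHB), deterministic
    builders for silica polymorph supercells, oxygen vacancies and polarizable
    water clusters, Ewald electrostatics for periodic cells, an
    electrostatic-embedding coupling layer with a pluggable Gaussian-density
    surrogate for the quantum subsystem, and trajectory analysis tools
    (structural averages, drift estimation, temperature statistics, vacancy
    formation energies).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
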