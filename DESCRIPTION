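Package: lnpsim
Title: Coarse-Grained Molecular Dynamics of Lipid Nanoparticle Self-Assembly
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained Martini-style coarse-grained molecular dynamics
    simulator and trajectory analysis toolkit for tripalmitin lipid
    nanoparticles with Tween 20 surfactant in coarse-grained water. Provides
    bead-level molecule topologies built programmatically, a configurable
    Lennard-Jones/bonded force field, system construction with solvation and
    energy minimization, a velocity-Verlet Langevin integrator with switched
    Lennard-Jones interactions, isotropic pressure coupling and periodic
    boundary conditions, and structural observables: radius of gyration,
    gyration-tensor asphericity, lipid number density, aggregate detection,
    interior-water classification with exchange tracking, and surfactant
    surface-coverage maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    igraph,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
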