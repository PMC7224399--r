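Package: diabodysim
Title: Mesoscale Coarse-Grained Models and Binding Kinetics of Polymer-Linked Nanobody Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coarse-grained bead models of diabodies (two nanobodies
    joined by a flexible polymer linker) in reduced Lennard-Jones units, either
    as rigid spheres (SPH) or by shape-based coarse graining (SBCG) of protein
    coordinates.  Samples wall-tethered molecules by overdamped Langevin
    (Brownian) dynamics or equilibrium Monte Carlo, reconstructs potentials of
    mean force from umbrella-sampling windows with WHAM, decomposes paratope
    height trajectories into flight and residence events to estimate
    second-binding on- and off-rates, and provides analytic tethered
    Gaussian-polymer references including persistence-length estimation and
    effective Kuhn-segment fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
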