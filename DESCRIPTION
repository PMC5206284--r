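Package: lamellipod
Title: Bistability Analysis of a Planar Actin-Myosin Lamellipodium Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and steady-state analyzer for a reduced mechanical model
    of the lamellipodium, the thin actin-filament sheet that drives cell
    crawling. Two transversal filament families interact through transient
    cross-links and myosin-II motor filaments; in the rigid-filament, planar
    limit the network reduces to a small ODE system for the filament angle and
    the leading-edge position. The package provides the age-structured
    transient-linker kinetics and the resulting angle-dependent effective
    stiffnesses with a cutoff angle, the single planar-lamellipodium ODE with
    its four equilibria and their stability, the coupled back-to-back
    two-lamellipodia fragment model with its symmetric (stationary) and
    polarized (moving) steady states, eigenvalue perturbation analysis of the
    size-angle coupling, parameter sensitivity reports, trajectory
    integration with basin classification, and an independent rigid-filament
    force/torque-balance quadrature oracle certifying the closed-form
    right-hand sides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
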