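Package: cyclicell
Title: Cyclic Homeostatic Ensemble and Langevin Kinetics for Adherent Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-mechanics modelling of adherent cells on stiff,
    cyclically strained substrates. Cells are represented as uniform
    elliptical morphological microstates carrying an angular distribution of
    contractile stress fibers with Hill-type rate sensitivity. The package
    computes cycle-averaged cell free energies, solves the homeostatic
    (constrained maximum-entropy) ensemble for the equilibrium distribution
    of cell shape and orientation, evaluates stress-fiber order statistics
    (circular variance, orientational order parameter), and simulates the
    stochastic evolution of cell morphology by overdamped Langevin dynamics,
    distinguishing reorientation by rigid rotation from reorientation by
    straining. Reduced fixed-circle and one-dimensional rod models are
    included for mechanistic attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
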