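Package: ferrosim
Title: Kinetic Modeling and Autoregulation of Iron Trafficking in Growing Yeast Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ODE-based kinetic model of cellular iron trafficking in
    exponentially growing budding yeast, with three cellular compartments
    (cytosol, mitochondria, vacuole), growth-dilution terms, and
    Michaelis-Menten/mass-action rate laws. Provides exact rational
    null-space analysis of the stoichiometric matrix to parameterize
    steady states from measured concentrations, soft-Heaviside logistic
    autoregulation of rate constants, stiff time integration and
    steady-state cell-state transitions, Jacobian eigenvalue stability
    analysis, local sensitivity analysis, and an evolutionary six-filter
    screen that selects viable cellular regulatory mechanisms (CRMs) from
    the combinatorial space of sensor assignments. The wild-type (W),
    Yfh1-deficient (Y), and iron-deficient (D) yeast states ship as a
    machine-readable model bundle; user-defined networks and states are
    supported through a structured text configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
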