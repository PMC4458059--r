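Package: tyroflux
Title: Growth-Coupled Strain Design, Pathway Thermodynamics and
    Fermentation Analytics for a Yeast Tyrosine Platform
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constraint-based metabolic modelling tools centred on
    growth-coupled knockout design for aromatic amino acid production in
    yeast. Provides a small stoichiometric model container with JSON and
    SBML readers, flux balance and flux variability analysis on a built-in
    bounded-variable simplex solver, the OptKnock bilevel knockout design
    MILP solved via strong duality and branch-and-bound, the GDLS local
    search heuristic with a two-step intermediate-target bootstrap, an
    exhaustive design oracle for small networks, reaction-quotient Gibbs
    energy profiling of the shikimate/tyrosine pathway from targeted
    metabolomics concentrations, growth and carbon-accounting calculations
    for fermentation time courses, and synthetic generators for toy models
    with verified coupled optima and simulated time courses with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, xml2, minpack.lm
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
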