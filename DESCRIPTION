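Package: ffrtree
Title: Lumped-Parameter Modelling of Fractional Flow Reserve in Branched
    Coronary Arteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Zero-dimensional (lumped-parameter) hemodynamic analysis of
    coronary vessel trees for virtual fractional flow reserve (FFR)
    estimation. Provides structured-tree microvascular outlet resistances
    with hyperemic scaling, a quadratic viscous-plus-expansion stenosis
    pressure-drop model, an exact ladder-network solver with fixed-point
    handling of flow-dependent stenosis resistance, closed-form circuit
    solutions for idealized branch configurations, virtual FFR pullback
    curves, with/without-side-branch comparisons, Murray's-law flow
    distribution checks, and a synthetic vessel-tree generator emulating
    OCT-pullback lumen profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
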