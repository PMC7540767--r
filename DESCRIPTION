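Package: rmphage
Title: Phage-Bacteria Ecosystems with Restriction-Modification Trade-Offs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates well-mixed ecosystems of bacterial strains that carry
    unique restriction-modification (RM) defence systems together with the
    epigenetic phage variants that evade them. Provides the coupled
    bacteria-phage differential equations with a compiled right-hand side, an
    open-ecosystem assembly protocol with periodic strain invasion and
    extinction culling, an analytic steady-state solver with an iterative
    community-assembly approximation, joint samplers of growth rate and RM
    imperfection implementing a growth-defence trade-off, and diagnostics
    including phage propagation probabilities, the burst-size diversity bound,
    and the effective-growth-to-imperfection fitness predictor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
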