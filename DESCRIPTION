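Package: doraswitch
Title: Dose-Response Alignment in Coupled GTPase Switch Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state analysis of a coupled monomeric/trimeric GTPase
    switch cascade with negative feedback from the distal switch onto the
    proximal GAP. Implements the six-variable kinetic model under mass-action
    or Hill kinetics with the feedback crosstalk modelled as an AND or OR
    logic gate, computes dose-response curves by stiff ODE integration,
    scalar fixed-point root-finding and closed-form expressions, and
    quantifies dose-response alignment (DoRA) with an area-between-curves
    distance metric. Includes parameter-space sweep pipelines for
    activation-level and feedback-strength analyses, matched-activation
    logic-gate comparison and cascade-length comparison, plus a seeded
    synthetic parameter generator and a config-driven experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
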