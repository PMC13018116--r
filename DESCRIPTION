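Package: lupusim
Title: Cell-Cell Interaction Modelling of Innate Immune Amplification in
    Lupus Nephritis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A response-time modelling framework for coupled immune cell and
    cytokine population dynamics, and a specific model of disease onset in
    lupus-prone (NZB/W F1) versus wild-type mice.  Cell infiltration,
    activation, proliferation under cytokine-mediated carrying capacities and
    Hill-gated cell-cell communication are combined with Erlang-distributed
    delays implemented by the linear chain trick.  Includes a hybrid
    deterministic-stochastic extension in which a telegraph process of acute
    inflammatory events drives immune-complex deposition, plus an in-silico
    experiment suite: feedback-loop knockouts, local sensitivity analysis,
    timed depletion therapy scans, virtual cohorts with log-normal parameter
    variation, and hybrid-model onset statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
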