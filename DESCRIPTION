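Package: latchSim
Title: Modelling of a Serine-Integrase Single-Input Binary Latch and
    Ripple Counter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic and stochastic models of a phiC31
    integrase/RDF DNA-inversion latch: an ODE model of pulsed integrase
    expression, state-dependent RDF expression with a TetR delay
    circuit, and directional PB/LR recombination; a stochastic
    plasmid-segregation and fluorescence model with flow-cytometry-like
    gating; a discrete per-pulse two-state toggle model and its N-latch
    binary ripple-counter extension; least-squares fitting of lumped
    protein production rates from fraction-LR time courses; and
    synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
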