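Package: gardsim
Title: Stochastic Simulation of GARD Micellar Reproduction with Order and
    Complexity Observables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the graded autocatalysis replication domain (GARD)
    model of compositional inheritance in amphiphile micelles as a stochastic
    growth-split constant-population reactor, together with the two
    observables used to track its evolutionary progression: the reciprocal
    sequential entropy of virtual random walks through the system (an order
    measure) and a combinatorial code-size estimate of Kolmogorov complexity.
    Includes composome detection, compotype clustering, takeover analysis,
    environment-shift protocols, engineered catalytic-network generators,
    and an end-to-end pipeline producing order-complexity trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
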