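Package: gjgate
Title: Markov Chain Models of Voltage Gating in Gap Junction Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds continuous-time Markov chain models of transjunctional
    voltage gating of gap junction channels from small hemichannel automata
    using Kronecker (tensor) algebra, including the generalized composition
    for state-dependent (functional) transition rates. Provides Boltzmann
    voltage-dependent subgate kinetics with conductance rectification and
    iterative voltage division across the two serial hemichannels, three
    channel model variants (12 two-state subgates, 6 three-state subgates,
    12 three-state subgates), four interchangeable steady-state solvers
    (dense Gaussian elimination, banded Gaussian elimination, a block
    recursive direct method, and warm-startable block Gauss-Seidel),
    exact operation-count complexity ledgers for comparing them, and a
    voltage-sweep driver producing steady-state junctional conductance
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
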