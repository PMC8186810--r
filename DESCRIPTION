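Package: bistablernn
Title: Bistable Recurrent Cells for Long-Lasting Memory in Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the bistable recurrent cell (BRC) and its recurrently
    neuromodulated variant (nBRC): gated recurrent units whose feedback gate can
    exceed unity, letting individual neurons become bistable and store
    information at the cellular level for arbitrarily long times. Provides the
    cell update rules with a standard GRU baseline, sequence unrolling with
    hand-written backpropagation through time, a dynamical-systems toolkit for
    the scalar cell map (fixed points, stability, bifurcation diagrams, and a
    numerical pitchfork-condition checker), generators for long-memory synthetic
    benchmarks (copy-first-input, denoising, and line-sequential MNIST
    transforms), a training harness with the ADAM optimizer, and gate-dynamics
    introspection utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
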