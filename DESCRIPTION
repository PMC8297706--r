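Package: fflscape
Title: Exact Steady-State Probability Landscapes and Multimodality of
    Feed-Forward Loop Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds stochastic reaction-network models of the eight types of
    transcriptional feed-forward loop (FFL) motifs, solves the discrete
    chemical master equation for their exact steady-state probability
    landscapes over truncated copy-number state spaces, and quantifies
    multimodality of the landscapes with zero-dimensional persistent homology
    of the superlevel-set filtration. Includes deterministic mass-action ODE
    comparators (occupancy-conditioned equilibria and mean-field steady
    states), a direct-method Gillespie simulator, phase-diagram sweeps over
    regulation intensities, input intensity, promoter binding dynamics and
    gene duplication, and analytic benchmark landscapes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    deSolve,
    igraph,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
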