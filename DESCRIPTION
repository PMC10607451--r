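Package: annealtomo
Title: Discrete Tomographic Reconstruction via Quadratic Binary Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for studying discrete (binary and small-integer) emission
    tomography reconstruction posed as quadratic binary optimization. Builds
    tomographic toy problems (procedural phantoms, parallel-beam sinograms and
    explicit system matrices), maps the least-squares reconstruction objective
    to QUBO, Ising and bounded-integer quadratic models, solves them with exact
    enumeration or a simulated-annealing sampler, and benchmarks the results
    against discretized filtered backprojection, DART and truncated
    Moore-Penrose pseudoinverse reconstructions under noise, underdetermination
    and inverse-crime-avoiding simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
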