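Package: dqqlp
Title: Multiscale Linear Optimization with a Double-Quad-Quad Simplex Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reliable solution of multiscale linear optimization problems,
    such as flux balance analysis of integrated metabolism and
    macromolecular expression (ME) models, whose data and solution values
    span many orders of magnitude.  Implements a precision-generic revised
    primal simplex method (IEEE double and 34-digit quadruple precision via
    compiled quadmath arithmetic) with sparse LU factorization,
    Bartels-Golub updates, basis repair and EXPAND anti-degeneracy, driven
    by a three-step Double-Quad-Quad procedure with warm starts that
    certifies primal and dual infeasibilities at the 1e-15 level on the
    original unscaled data.  Includes geometric-mean scaling, MPS
    input/output, flux-coupling constraints, coefficient lifting,
    stoichiometric-consistency screening, flux variability analysis,
    growth-rate bisection, a zoom refinement strategy, and seeded
    generators of multiscale test instances with exactly-feasible planted
    points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
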