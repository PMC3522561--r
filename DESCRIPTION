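Package: sdsolve
Title: Second-Derivative Implicit Integration of Stiff Reaction-Network ODEs
    with Parameter Sensitivities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An implicit integrator for stiff systems of ordinary differential
    equations as they arise from (bio)chemical reaction networks.  The method
    advances the solution with a degree-4 two-point rule that interpolates the
    state and its first and second time derivatives at both step endpoints,
    solved by a simplified Newton iteration with a single matrix factorization
    per step.  The local error is estimated from a degree-5 reference rule
    using one extra back-substitution with the already-factorized Newton
    matrix, and the step size is adjusted with a fifth-root controller.  Local
    parameter sensitivities are computed in a staggered, direct fashion after
    each accepted step: one factorization serves all parameters, and the fresh
    Jacobians can be re-used in the next step's Newton matrix.  A symbolic
    compiler generates all required derivative functions (Jacobian, second
    derivative, their parameter derivatives) from rate-law expressions or
    mass-action stoichiometry, emitting only structurally non-zero entries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
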