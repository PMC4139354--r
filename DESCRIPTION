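Package: ccpop
Title: Coupled Population and Carrying-Capacity Difference-Equation Models
Version: 1.0.0
Authors@R: person("ccpop", "maintainers", email = "ccpop@example.org",
    role = c("aut", "cre"))
Description: Simulates, calibrates, and analyses discrete annual-step models of
    global human population growth in which carrying capacity is an elastic,
    history-dependent state variable coupled to population change. Implements
    the classic Verhulst logistic baseline, Cohen's original coupled model
    (dP = r*P*(K-P), dK = (L/P)*dP), and a consumption-cost extension in which
    a nonlinear consumption term erodes carrying-capacity gains at large
    population sizes. Provides bisection calibration of the unobserved initial
    carrying capacity against an intermediate anchor, trajectory-to-history
    fit metrics, grid-search sensitivity scans over the limit to economies of
    scale L and the consumption-cost coefficients (a, b), a cost-law
    identification harness, synthetic observation generators for parameter
    recovery experiments, equilibrium and elasticity diagnostics, and a
    command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
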