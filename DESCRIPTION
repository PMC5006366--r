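Package: robustoc
Title: Robust Dynamic Optimization of Kinetic Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic optimization of kinetic biological-network ODE models
    under parametric uncertainty. Chance constraints and objectives are
    reformulated with backoff terms whose expected values and variances are
    computed by one of three uncertainty-propagation techniques
    (sensitivity-equation linearization, sigma points / unscented transform,
    or polynomial chaos expansion regression). The optimal-control problem is
    transcribed by orthogonal collocation on Radau points and solved by an
    augmented-Lagrangian nonlinear-programming method; two-objective
    trade-offs are computed by Normal Boundary Intersection, and resulting
    control profiles are validated by Monte-Carlo simulation. Two kinetic
    pathway case studies (a three-step linear pathway with mass-action
    kinetics and a glycolysis-inspired branched network with
    Michaelis-Menten kinetics) ship as built-in model fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
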