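Package: antiwindup
Title: Antithetic Integral Feedback Control with Biomolecular Anti-Windup Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for antithetic integral feedback
    (AIF) control of chemical reaction networks. Provides deterministic ODE and
    exact stochastic (Gillespie) simulation of reaction networks with
    piecewise-constant disturbance schedules; quasi-steady-state model
    reduction of fast sequestration reactions with sup-norm and L1 discrepancy
    diagnostics and fixed-point lifting; the steady-state admissibility
    calculus for setpoints and disturbances under actuator and sensor
    saturation; classical and antithetic integral controllers with Hill-type
    saturations and fixed-point existence analysis; sequestration-based
    biomolecular threshold switches; three anti-windup topologies (conditional
    integration and reference/sensor conditioning) in both phenomenological
    and full reaction-network form; and scenario fixtures plus a command-line
    interface that reproduce windup and anti-windup simulations from printed
    parameter sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
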