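# antiwindup

Simulation and analysis toolkit for **antithetic integral feedback (AIF)
control** of chemical reaction networks, and for **biomolecular anti-windup
circuits** that protect such controllers when actuation or sensing
saturates.

## Who this is for

Synthetic biologists and control theorists designing genetic integral
controllers. An AIF controller — two species **Z1**, **Z2** that sequester
each other at rate η — delivers robust perfect adaptation (RPA): the
regulated output returns to the setpoint `r_in = μ/θ` (as read through the
sensing function) despite constant disturbances. But molecular actuation is
production-only and saturates, so when a disturbance or setpoint demand is
infeasible, a controller species accumulates without bound — *integral
windup* — and performance stays poor long after the disturbance recedes.

## What the package computes

The closed loop is

```
process:     ẋ = f_Δ(x) + u e₁,   y = x_L
controller:  ż₁ = μ − η z₁ z₂
             ż₂ = θ hₛ(y) − η z₁ z₂
actuation:   u  = k hₐ(z₁)
```

and the package provides:

* **Simulation substrate** (`reaction_network`, `simulate_ode`,
  `simulate_ssa`, `find_steady_state`): stiff-capable deterministic ODEs and
  exact Gillespie sampling of the same network object, with
  piecewise-constant disturbance schedules and divergence detection.
* **Model reduction** (`reduce`, `discrepancy`, `convergence_study`,
  `lift_fixed_point`, `full_fixed_point`): in the fast-sequestration limit a
  pair (Z1, Z2) collapses onto the positive/negative parts of one signed
  coordinate z with drift `W₁ − W₂`; the package quantifies the convergence
  (sup-norm and L1 metrics) and transfers fixed points between the full and
  reduced descriptions.
* **Admissibility calculus** (`io_map`, `supporting_input`,
  `admissible_setpoints`, `admissible_disturbances`,
  `admissible_input_setpoints`, `fixed_point_exists`): for affine
  steady-state maps `ȳ = α ū + β`, the setpoints and disturbances that admit
  a feasible supporting input — a controller-independent feasibility test.
* **Sequestration switches** (`seq_switch`, `sweep_response`): biomolecular
  comparators whose strong-sequestration steady state is the
  threshold-linear map `max(u − u₀, 0)/δ₂`.
* **Anti-windup topologies** (`closed_loop_antiwindup`,
  `reduced_conditional_integration`, `steady_state_error`,
  `conditioning_factors`, `windup_metrics`): conditional integration
  (topologies I/II — extra production or self-degradation of the controller
  species past a threshold, a leaky integrator outside the safe band
  `[−kβᵢ, kβⱼ]`) and reference/sensor conditioning (topology III), as full
  reaction networks and as reduced phenomenological models.
* **Scenario fixtures and a CLI** (`get_scenario`, `run_cli`,
  `inst/cli/antiwindup.R`): canonical windup/anti-windup demonstrations with
  machine-checkable expected outcomes, plus `simulate`, `steady-state`,
  `admissibility`, `reduce` and `scenario` subcommands over YAML configs.

## Worked example

The saturated loop: unit-rate gene expression under a constant basal
disturbance Δ = 5, controlled with μ = 10, θ = 15, η = 100, k = 8 and Hill
actuation/sensing with κa = κs = 5.

```r
library(antiwindup)

proc <- gene_expression_process(k1 = 1, gamma1 = 1, gamma2 = 1, Delta = 5)
sats <- make_saturations("hill", "hill", kappa_a = 5, kappa_s = 5)
loop <- closed_loop_aif(proc, mu = 10, theta = 15, eta = 100, k = 8, sats = sats)
find_steady_state(loop, rep(0, 4), t_max = 2000, tol_rel = 0, tol_abs = 1e-9)
#> <steady_state_result> status: converged  t: 240
#> residual: 6.855e-10
#>       X1       X2       Z1       Z2
#> 10.00000 10.00000  8.33333  0.01200
```

The output settles at 10: the input setpoint is `r_in = μ/θ = 2/3` and the
sensing function maps it to the output setpoint `hₛ(r_out) = 2/3 ⟹ r_out =
10`. The actuator state `Z1 = 25/3` supplies `u = 8·hₐ(25/3) = 5`, exactly
the supporting input `r_out − Δ`. Feasibility is an algebraic question:

```r
admissible_setpoints(io_map(proc), interval(0, 8))
#> <interval> [5, 13]
admissible_disturbances(function(D) io_map(proc, Delta = D), r = 10,
                        U = interval(0, 8))
#> <interval> [2, 10]
```

so output setpoints outside [5, 13] — or disturbances outside [2, 10] at
setpoint 10 — admit no supporting input and *no controller whatsoever* can
track them: the loop winds up instead (`find_steady_state` reports
`diverged`). The strong-sequestration reduction that underpins the
anti-windup analysis converges at rate ~1/η:

```r
spec <- aif_fast_seq_spec(gene_expression_process(), mu = 10, theta = 1,
                          eta = 100, k = 1)
convergence_study(spec, c(10, 100, 1000), T = 20)
#>    eta  sup_metric  l1_metric
#> 1   10 0.279284818 3.10994133
#> 2  100 0.028042793 0.31191063
#> 3 1000 0.002805387 0.03119983
```

The paired windup demonstration — topology I versus the bare loop under an
inadmissible disturbance pulse — is a one-liner per arm:

```r
check_scenario("antiwindup")     # dormancy, setpoint hold, fast recovery
tr_on  <- run_scenario("antiwindup")
tr_off <- run_scenario(scenario_antiwindup(FALSE))
max(tr_on$states[, "Z2"]) / max(tr_off$states[, "Z2"])   # ≈ 0.17
```

The same scenarios are scriptable from a shell:

```sh
Rscript inst/cli/antiwindup.R scenario --list
Rscript inst/cli/antiwindup.R scenario --name antiwindup --check
Rscript inst/cli/antiwindup.R admissibility --config my-process.yaml
```

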