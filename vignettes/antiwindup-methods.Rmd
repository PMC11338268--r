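---
title: "Models and methods: antithetic integral feedback and biomolecular anti-windup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: antithetic integral feedback and biomolecular anti-windup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antiwindup)
```

## The control problem

Robust perfect adaptation (RPA) is the property that a regulated variable
returns to a fixed setpoint at steady state despite constant disturbances and
parameter uncertainty. In synthetic biology it is achieved with integral
feedback, and the canonical reaction-network realization is the antithetic
integral feedback (AIF) controller: two species $Z_1$ and $Z_2$ that
annihilate each other,

$$\dot z_1 = \mu - \eta z_1 z_2, \qquad
  \dot z_2 = \theta\, h_s(y) - \eta z_1 z_2, \qquad
  u = k\, h_a(z_1),$$

closed around a process with input $u$ (a production rate into the first
process species) and output $y$ (the last process species). The difference
$z = z_1 - z_2$ integrates the sensed error: $\dot z = \mu - \theta h_s(y)$,
so any stable steady state pins $h_s(\bar y) = \mu/\theta \equiv r_\mathrm{in}$.

Because concentrations cannot be negative and because actuation and sensing
saturate (Hill kinetics, promoter saturation), the integrator can *wind up*:
when the demanded actuation is infeasible, one controller species accumulates
without bound, and even after the disturbance recedes the loop spends a long
time "unwinding". This package implements (i) the algebra that decides when
a setpoint/disturbance pair is feasible at all, (ii) a model-reduction
calculus that maps sequestration networks onto classical saturated integral
control, and (iii) three biomolecular anti-windup topologies, in both
phenomenological and full reaction-network form.

## Model reduction for fast sequestration

A system with one fast sequestration pair is written with an arbitrary
subnetwork $x$ and aggregate production/removal maps $W_1, W_2$:

$$\dot x = F(x, z_1, z_2),\quad
  \dot z_1 = W_1 - \eta z_1 z_2,\quad
  \dot z_2 = W_2 - \eta z_1 z_2 .$$

As $\eta \to \infty$ the pair collapses onto the positive and negative parts
of one signed coordinate $z$ with drift $W_1 - W_2$ evaluated at
$(x, z^+, z^-)$, where $z^+ = \max(z, 0)$ and $z^- = \max(-z, 0)$. The
package quantifies the approach with two metrics on a common interpolation
grid over $[0, T]$:

* the sup over time of the $\ell^2$ distance between $(x, z_1 - z_2)$ and
  $(x, z)$, and
* the time integral of the $\ell^2$ distance between $(x, z_1, z_2)$ and
  $(x, z^+, z^-)$.

Both converge to zero as $\eta$ grows. Fixed points transfer the same way:
a reduced fixed point $(\bar x, \bar z)$ lifts to
$(\bar x, \bar z^+, \bar z^-)$, the unique limit point of nonnegative
full-system fixed points, and if the reduced system has no fixed point then
the full system has none (for large $\eta$) either — in simulation this
manifests as unbounded growth of a controller species.

Numerical choices: the $\ell^2$ norm throughout; trapezoidal quadrature for
the integral metric on a grid of at least 2,000 points per horizon (stable
under grid doubling); full-system fixed points are located by a Newton-type
solver (`pracma::fsolve`) started from the lifted reduced fixed point, which
is the natural initial guess because it is the unique limit point.

One degeneracy is worth recording. For a standalone sequestration switch
with *equal* degradation rates $\delta_1 = \delta_2$, the signed difference
$z_1 - z_2$ satisfies the reduced equation exactly at *every* $\eta$, so the
sup metric is identically zero and a convergence study built on it would
measure solver noise. The shipped convergence study of the switch therefore
uses unequal rates ($\delta_1 = 1.5$, $\delta_2 = 0.5$), which break the
closure and make both metrics informative. The anti-windup circuits
themselves keep the unit rates used everywhere else.

## Admissibility: what any controller can and cannot do

Feasibility is a property of the process, not the controller. For a stable
unimolecular process $\dot x = SWx + Sb + e_1 u$, $y = e_L^\top x$, the
steady-state input/output map is affine,
$\bar y = \alpha \bar u + \beta$ with
$\alpha = -e_L^\top (SW)^{-1} e_1 \ge 0$ and
$\beta = -e_L^\top (SW)^{-1} S b \ge 0$
(nonnegativity follows from the Metzler-plus-Hurwitz structure). The
*supporting input* of a setpoint $r$ is $\bar u = (r - \beta)/\alpha$; the
setpoint is *admissible* when $\bar u$ lies in the feasible-input set $U$.
For gene expression ($\alpha = k_1/\gamma_1\gamma_2$,
$\beta = k_1\bar\Delta/\gamma_1\gamma_2$) with production-only actuation
bounded by $k$, the admissible output setpoints are
$[\,\beta,\; \alpha k + \beta\,]$ and the admissible disturbances for a
setpoint $r$ are $[\,\gamma_1\gamma_2 r/k_1 - k,\; \gamma_1\gamma_2 r/k_1\,]$
intersected with the feasible disturbances. With saturating sensing the
input and output setpoints are linked by $h_s(r_\mathrm{out}) =
r_\mathrm{in}$, and admissible input setpoints are the image
$h_s(\cdot)$ of the admissible output setpoints.

Interval conventions: finite endpoints attained by a feasible input are
closed, infinite endpoints open. Supporting inputs of monotone non-affine
maps are found by bracketed root-finding with a doubling bracket capped at
$10^{12}$; non-monotone maps are rejected rather than silently returning one
of several roots, which enforces uniqueness of the supporting input.
Admissible-disturbance sets exploit monotonicity of the supporting input in
the disturbance: the boundaries are located by bisection on the crossings of
the feasible-input bounds.

The fixed-point existence report checks the three algebraic conditions —
setpoint admissible, sensor unsaturated at steady state, actuator
unsaturated at steady state — and returns the closed-loop fixed point
$(\bar y, \bar u, \bar v, \bar w)$ when all hold. Conditions holding exactly
at a range boundary are reported as existing with a boundary note, since the
open/closed convention at saturation edges is a modeling choice with measure
zero.

The effective actuation nonlinearity of the reduced loop is taken as
$\psi_a(v) = k\, h_a(\max(v, 0)/k)$ with $v = kz$; this is exactly the
actuation law of the reduced controller $u = k h_a(\max(z,0))$ rewritten in
the intermediate variable, and with identity $h_a$ it degenerates to the
one-sided saturation $\max(v, 0)$ of the unsaturated antithetic motif.

## Anti-windup topologies

All three topologies attach two sequestration switches to the controller. A
switch is a pair $V_1, V_2$ with
$\dot v_1 = u_0 - \eta_v v_1 v_2 - \delta_1 v_1$,
$\dot v_2 = u - \eta_v v_1 v_2 - \delta_2 v_2$: in the strong-sequestration
limit its steady output is the threshold-linear map
$\bar v_2 = \max(u - u_0, 0)/\delta_2$, i.e. a biomolecular comparator with
threshold $u_0$ and post-threshold slope $1/\delta_2$.

* **Topology I** (conditional integration, cross-production): high $Z_2$
  drives extra production of $Z_1$ at rate $h_1(v_2)$ and vice versa. The
  anti-windup production is injected as a direct mass-action production of
  $Z_1$, not routed through the actuation nonlinearity — it is a separate
  reaction in the network realization.
* **Topology II** (conditional integration, self-degradation): each $Z_i$
  is degraded with propensity $h_i(\cdot)\, z_i$ once its own level crosses
  the threshold; for linear readouts the limiting propensity at
  $\bar z_1 = v_0 + c$ is $\alpha_1 c (v_0 + c)$ — quadratic past the
  threshold.
* **Topology III** (reference/sensor conditioning): production of $Z_1$ is
  repressed by $V_2$ through a decreasing Hill readout. The package pins
  $h_1(0) = \mu$ so the unswitched regime reproduces the nominal setpoint
  rate exactly (any other normalization would silently move the setpoint),
  and scales the sensing rate by a unit-normalized repression factor for the
  symmetric branch; the half-repression constant is the tuning knob.

Switch drive signals are the instantaneous controller species (identity
input maps by default); topology I feeds the $v$-switch with $z_2$ and the
$w$-switch with $z_1$, topologies II/III feed each switch with its own
species.

In the strong-sequestration limit of both the controller pair and the
switch pairs, topologies I and II reduce to a *conditional integrator* on
$v = k(z_1 - z_2)$ with error $e = r_\mathrm{in} - h_s(y)$ and
$K_I = k\theta$:

$$\dot v = K_I e - \alpha_i (v + k\beta_i) \;\; (v < -k\beta_i), \qquad
  \dot v = K_I e \;\; (\text{inside}), \qquad
  \dot v = K_I e - \alpha_j (v - k\beta_j) \;\; (v > k\beta_j),$$

with $(i, j) = (1, 2)$ for topology I and $(2, 1)$ for topology II: a pure
integrator inside the safe band and a leaky integrator outside it. The
steady-state error is then proportional to the excursion:
$\bar e = (\alpha_i/K_I)(\bar v + k\beta_i)$ below the band, zero inside,
$(\alpha_j/K_I)(\bar v - k\beta_j)$ above — continuous at both edges. The
outer-branch form was chosen symmetric to the band edges precisely so that
setting $\dot v = 0$ reproduces this error formula; this is the only
self-consistent reading, and the unit suite verifies the equivalence of the
piecewise implementation with the switch-reduction composition on random
states. Topology III reduces instead to dynamic scaling of the reference
(for high positive $v$) or of the sensed signal (for low negative $v$) by
the factors $k\alpha_1/(k\alpha_1 + v - k\beta_1)$ and
$k\alpha_2/(k\alpha_2 - v - k\beta_2)$, both in $(0, 1]$.

### The finite-rate switch leak

At finite switch sequestration rates the comparator is not exact: below
threshold its output is small but nonzero,
$\bar v_2 \approx u / (\eta_v \bar v_1 + \delta_2)$. In topology I this leak
enters the integral balance
$\theta h_s(\bar y) = \mu + h_1(\bar v_2) - h_2(\bar w_2)$ and biases the
steady output. At the shipped anti-windup parameters
($\eta_v = \eta_w = 100$, thresholds 10 and 20, identity readouts) the bias
is about 0.2% of the setpoint (output $\approx 9.979$ instead of 10), and it
shrinks like $1/\eta_w$. Adaptation is therefore preserved *approximately*
by the full reaction-network circuitry — exactly only in the
strong-sequestration limit. The test suite asserts the $1/\eta$ shrinkage
and the sub-1% dormancy of the switch species rather than exact setpoint
recovery; an idealized exactness tolerance of $10^{-6}$ is not attainable by
the full network at these rates, which the acceptance suite reports
honestly.

## Simulation machinery and numerical choices

* Deterministic dynamics use `deSolve::lsoda` with `rtol = 1e-8`,
  `atol = 1e-10`; sequestration rates up to $10^4$ make the systems stiff
  and lsoda switches to its implicit method automatically.
* Disturbance schedules are piecewise constant and right-continuous; the
  integrator is restarted at every breakpoint so steps are never smoothed
  over, and output times within $10^{-9}$ of a breakpoint are snapped onto
  it to avoid degenerate sub-tolerance output intervals.
* States within $10\cdot$`atol` below zero are clipped to zero; larger
  negative excursions are left visible because they indicate a modeling
  error, and every shipped scenario is tested to stay above
  $-10\cdot$`atol`.
* Steady states are found by chunked integration until
  $\|\dot x\| < \mathrm{tol}_\mathrm{rel}\|x\| + \mathrm{tol}_\mathrm{abs}$
  past the last schedule breakpoint. Divergence is declared when a state
  exceeds $10^9$, or when at the time horizon a state has grown
  monotonically over the last 20% of the horizon with a late-window slope at
  least half the early-window slope — sustained (linear or faster) growth is
  the signature of a nonexistent nonnegative fixed point, while a saturating
  approach has a decaying slope and is reported as `max_time`.
* The stochastic simulator is the exact Gillespie direct method with
  propensities re-evaluated after every jump and the chain restarted at
  schedule breakpoints; it is seeded explicitly and reproducible.
* Closed-loop initial conditions default to all-zero states, the convention
  for all shipped scenarios; they are overridable in configs.
* Controller dilution is off by default (it makes the integrator leaky); an
  optional first-order dilution rate is accepted.

## Scenario design

The scenario fixtures carry the canonical parameter sets: the unsaturated
loop at $\mu = 10$, $\eta = 100$, $k = \theta = k_1 = \gamma_1 = \gamma_2 =
1$ (setpoint 10, admissible disturbances $[0, 10]$), and the saturated loop
at $k_1 = \gamma_1 = \gamma_2 = 1$, $\eta = 100$, $\theta = 15$, $k = 8$,
$\kappa_a = \kappa_s = 5$ (output setpoint 10, admissible output setpoints
$[5, 13]$, admissible disturbances $[2, 10]$), with anti-windup topology I
at $\eta_v = \eta_w = 100$, $v_0 = 10$, $w_0 = 20$, unit switch degradation
rates and identity switch maps.

The exact plotted schedules are not part of the printed parameter sets, so
the fixtures choose steps that cross the analytically derived admissibility
boundaries with plateaus of at least 50 time units, long enough for steady
states to be observable. The anti-windup demonstration uses a 60-time-unit
disturbance pulse 50% beyond the admissible ceiling ($\Delta: 5 \to 15 \to
5$). The pulse length matters: the protected loop clamps $z_2$ near the
switch threshold $v_0$, while the unprotected loop accumulates $z_2$ at a
constant rate ($\approx \theta h_s(15) - \mu = 1.25$ per time unit), so a
pulse much shorter than $\sim\!50$ units would not build up enough windup
for the paired comparison to be meaningful. Sixty units matches the plateau
convention of the other fixtures.

Problem sizes were chosen so the whole suite runs on a laptop in about two
minutes: horizons of 300–320 time units on 1,501-point output grids for the
scenarios, convergence studies over $\eta \in \{1, 10, 100, 1000\}$ on
2,001-point grids, a 50-point input sweep for the switch response, and 500
stochastic paths per arm for the full-versus-reduced switch distribution
comparison (two-sample Kolmogorov–Smirnov at the 5% level).

What the scenarios emulate — and what they do not: they are deterministic
(or exact-SSA) simulations of well-mixed mass-action kinetics with
parameters known exactly. Real implementations add cell-to-cell
variability, resource competition between the controller and the host,
dilution of all species by growth, and uncertain, time-varying rates; none
of these are modeled here (dilution is available but off by default).
Passing fixtures therefore validate the mathematics of the designs, not
their in-vivo performance.

## Known limitations

* Reduction handles one fast sequestration pair per application; topologies
  with two switches are reduced pairwise, which is standard practice but
  not covered by a joint limit theorem when the rates differ.
* Processes are single-input single-output with monotone steady-state maps;
  set-valued inverse maps are out of scope.
* No SBML import/export, no spatial models, no tau-leaping or hybrid
  stochastic schemes.
* The conditional-integration reduction is implemented for topologies I and
  II; topology III is reduced to the conditioning factors only.
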