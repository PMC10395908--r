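---
title: "Efficiency limits of non-processive motor ensembles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficiency limits of non-processive motor ensembles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorlimits)
```

## The model

`motorlimits` implements a mechano-chemical crossbridge model of a
non-processive motor of the myosin family, in the tradition of T. L. Hill's
formalism. A motor cycles through $N_S = N_B + 2$ chemical states: it binds
to the track carrying ADP and inorganic phosphate, progresses through $N_B$
bound conformations (product release, working stroke, rigor), detaches upon
binding a fresh ATP, and re-primes its lever (recovery stroke) while
hydrolyzing ATP in the detached state. Each state $i$ carries a free energy
$G_i$ and an unstrained lever position $d_i$; the elastic element connecting
the head to its filament stores energy $U_i(x) = U(x - d_i)$ at strain
coordinate $x$. Completing a cycle consumes one ATP with free energy
$\Delta G_{\mathrm{ATP}}$ (about $-25\,k_BT$ under physiological
conditions).

Everything is dimensionless: energies in $k_BT$, distances in units of the
working stroke $d$, rates in units of the maximal ATP-induced detachment
rate $k^{\max}_{+\mathrm{ATP}}[\mathrm{ATP}]$. For a harmonic element with
physical stiffness $K$ the key dimensionless group is
$\kappa = K d^2 / k_BT$, conventionally quoted as $\kappa/2$ (the elastic
energy stored over one working stroke); $K = 3$ pN/nm, $d = 8$ nm and
$k_BT = 4$ pN nm give $\kappa/2 = 24$ (`nondimensionalize()`).

Transition rates between neighbouring states are
$k_i(x) = k_i^0 e^{-\alpha_i \Delta U_i(x)}$ forward and
$k_{-i}(x) = k_i^0 e^{G_{i+1} - G_i} e^{(1 - \alpha_i)\Delta U_i(x)}$
backward, where $\Delta U_i = U_{i+1} - U_i$ and $\alpha_i \in [0, 1]$
distributes the elastic load between the two directions. Their ratio always
satisfies generalized detailed balance; reverse bare rates are never free
parameters. Attachment carries $\alpha = 1$ (the detached head must stretch
thermally to reach a binding site; detachment back from the first bound
state is strain-independent) and ATP-induced detachment carries
$\alpha = 0$.

Two conventions deserve comment because the published material leaves them
open:

* **Detached lever positions.** We tie the detached states' lever positions
  to their bound neighbours ($d_0 = d_1$, $d_{N_B+1} = d_{N_B}$; the
  recovery stroke completes while detached). With $\alpha_0 = 1$ this choice
  is provably inert: the attachment flux density is
  $k_0^0 e^{-U_1(x)}/Z$ regardless of $d_0$, because the Boltzmann weight of
  the detached head and the strain factor of the attachment rate combine to
  the same product. The convention only simplifies bookkeeping.
* **Hydrolysis between the detached pools.** Both detached states are
  thermally equilibrated, and because the same elastic potential applies in
  every state their configurational partition functions are identical; the
  hydrolysis step is therefore treated at pool level with a single rate
  (`k_hyd`). It sets the duty ratio but cancels from the efficiency; the
  default ($10^5$) keeps the detached dwell negligible, and stochastic
  simulations should use a moderate value so that event counts stay
  manageable.

## Stationary solver

At constant sliding velocity $v$ the bound densities obey
$-v\,\partial_x P_i = j_{i-1}(x) - j_i(x)$ with flux densities
$j_i = k_i P_i - k_{-i} P_{i+1}$ and boundary condition
$P_i(x \to \infty) = 0$. The solver exploits linearity: two basis problems
(unit occupancy in each detached pool) are integrated downward in $x$ with a
non-adaptive 3-step backward differentiation formula (startup with the one-
and two-step formulas), and the system is closed by pool stationarity plus
normalization — a $2 \times 2$ linear solve. The scheme is implicit, which
is what the stiff strain-dependent rates require; each step solves a small
banded system shared by both basis problems.

Numerical choices, all validated by the test suite:

* **Grid.** Step $\Delta x = \min(\sqrt{1/\kappa}/50,\ 1/400)$ resolves the
  sharpest thermal length by a factor of 50. The upper bound sits where the
  Boltzmann attachment weight has fallen to $e^{-40}$; the lower bound is
  generous and integration stops once the bound densities have decayed to
  $10^{-14}$ of their running maximum. If mass remains at the hard floor the
  solver raises an error instead of silently truncating. Halving the step
  changes the efficiency by well under $10^{-4}$ on all packaged parameter
  sets, and the energy-balance residual converges at third order.
* **Quadrature.** Composite Simpson weights on the solver grid (the
  trapezoid rule would limit the energy-balance identity to about
  $10^{-5}$; Simpson keeps it near $10^{-8}$ at the default step).
* **Entropy production in log space.** The dissipation density of
  transition $i$ is $(a - b)(\ln a - \ln b)$ with $a, b$ the directed
  one-way fluxes — manifestly non-negative pointwise. The logs of the pool
  densities are evaluated analytically ($\ln \rho = -U(x) - \ln Z$), never
  through `exp()`: a deeply strained head that detaches carries an entropy
  cost proportional to $U(x)$, and representing $e^{-U}$ in double
  precision would silently drop exactly that contribution once $U \gtrsim
  700$. This was the single largest numerical pitfall in the development of
  the package.
* **$v = 0$.** The advection term vanishes and the states decouple into
  local linear systems per grid point plus the pool closure; the solver
  switches to that algebraic path. Lengthening ($v < 0$) is out of scope
  and rejected.

From the solved field the package reports the conserved cycle flux
(`r_ATPase`, identical across transitions to $\sim 10^{-10}$), the mean
force per motor $F = \sum_i \int P_i U_i'\,dx$, the per-transition
entropy-production map, and the efficiency
$\eta = v F / (r_{\mathrm{ATPase}} \cdot |\Delta G_{\mathrm{ATP}}|)$, which
satisfies the energy balance
$T\dot S = -vF + r_{\mathrm{ATPase}}|\Delta G_{\mathrm{ATP}}|$ as an
internal consistency check.

```{r solve-example}
fx <- motor_fixture("nb2_optimal")
field <- solve_stationary(fx$cycle, fx$potential, fx$v)
field
```

## Elastic potentials

Three convex shapes with $U(0) = 0$, $U'(0) = 0$ are supported: harmonic;
a two-regime form that is stiff ($U'' = \kappa$) above a transition point
$x_a \le 0$ and perfectly compliant below it (constant pushing force, the
buckling-type asymmetric element seen in single-molecule experiments); and
a free piecewise-quadratic shape with per-segment curvatures in
$[0, \kappa]$, used for functional optimization of the potential. The
two-regime form converges to the harmonic one as $x_a \to -\infty$. A
potential whose tails do not grow (zero curvature and zero slope) would
make the detached Boltzmann density unnormalizable and is rejected at
construction.

## Optimization scenarios

Three study designs are expressed as `motor_scenario()` objects, differing
in what is fixed, free, and capped:

* **Free velocity**: maximize the peak of the $\eta$–$v$ relation over
  velocity, bound-state free energies, bare rate ratios, load-distribution
  coefficients, intermediate lever positions, and stiffness up to a cap.
  The detachment rate is the rate unit. By convention $G_1 = 0$ (the
  bound-detached offset only moves the duty ratio) and the full hydrolysis
  drop sits across the attachment–detachment leg.
* **Fixed force, stable**: additionally require the operating point to lie
  outside the hysteresis of the force–velocity relation. We operationalize
  this as $F(v^\*) \le \min_{v < v^\*} F(v) - \delta$ on a velocity grid
  that covers the near-stall region with log-spaced points
  ($\delta = 10^{-4}$): the operating force must be carried at no slower
  velocity, so under constant load the velocity is unique. The nonlinear
  constraint is handled by sequential quadratic-penalty passes with
  increasing weight, warm-started — the same role the reference
  implementations assign to an SQP routine.
* **Fixed velocity**: maximize $\eta$ at a prescribed $v$ under caps on the
  two second-order binding rates (ATP-induced detachment, and ADP binding
  expressed relative to the ATP rate, physiologically about 1/100). The
  ADP cap constrains the *reverse* of the ADP-release transition; through
  detailed balance this bounds its bare forward rate given the free-energy
  difference, so the cap is implemented exactly by reparameterizing the
  optimization in terms of the ADP-binding rate itself.

All drivers use seeded Latin-hypercube multi-starts (rates in log space,
coefficients and lever fractions in boxes), bounded quasi-Newton refinement
(`optim(method = "L-BFGS-B")`), and simplex polish of the best candidates;
a fixed seed reproduces the full trajectory. Parameter scans
(`continuation_scan()`) warm-start each point from its solved neighbour in
both directions, which is essential in practice: the efficiency landscape
has well-separated basins (the near-equilibrium optimum, for instance, is
found from cold starts only rarely, but continuation in
$-\Delta G_{\mathrm{ATP}}$ tracks it reliably).

Functional optimization of the potential (`optimize_potential_shape()`)
makes the per-segment curvatures of a 16-segment piecewise potential on
$[-1.5, 1.5]$ ordinary box-bounded parameters, always including a
harmonic-at-the-cap start (a feasible point, so the anharmonic optimum can
never fall below the harmonic one); the resulting shape is summarized by
the best-fitting two-regime form and its transition point.

## Stochastic validation

`simulate_ensemble()` runs an exact Gillespie simulation of $N_m$ motors on
a rigid common filament against a constant total load, with instantaneous
mechanical re-equilibration after every reaction event (the filament
position solves $\sum_m U'(x_m + \delta) = F_{\mathrm{load}}$, a
one-dimensional convex root). Attachment strains are drawn from the exact
Boltzmann density (normal for harmonic potentials, inverse-CDF tables
otherwise). The event loop is compiled; propensities are refreshed after
every event, and R's RNG drives everything, so a seed fixes the trace
bit-for-bit.

Two caveats that the tests make explicit:

* Agreement with the stationary solver holds at operating points where the
  force–velocity relation is single-valued: there, a 50-motor ensemble
  reproduces the stationary efficiency and velocity within Monte-Carlo
  error, and the long-run ATP consumption matches $N_m r_{\mathrm{ATPase}}$.
  Near or inside the anomalous (positive-slope) region a finite ensemble
  under constant load genuinely rattles between branches or escapes — the
  instability that motivates the fixed-force scenario — so no convergence
  to the fast branch should be expected there. We verified this directly: a
  100-motor ensemble loaded a few percent below the deterministic stall
  force of a thin-margin "stable" optimum is dragged backward within a few
  hundred time units.
* Exact simulation of near-equilibrated fast transitions (bare rates
  $\gtrsim 10^6$) is prohibitively event-hungry; cycles built for
  simulation should use moderately fast bound-bound rates, which leave the
  observables nearly unchanged (the stationary solver quantifies the
  residual dependence).

## Soft-spring analytics

In the soft-spring limit $\kappa d^2 \ll |\Delta G_{\mathrm{ATP}}|$ the
rates lose their strain dependence and the cycle admits closed forms: the
unloaded velocity $v_{\max} = 2d(1 - 1/N_B)/t_{\mathrm{on}}$ for the
optimal structure (fast first transition carrying the full stroke, equal
remaining rates), a linear force–velocity relation with stall force
$\kappa t_{\mathrm{on}}/t_{\mathrm{cycle}}$, work per ATP
$\tfrac{1}{2}\kappa(1 - 1/N_B)$, and efficiency
$\eta = \kappa(1 - 1/N_B)/(2|\Delta G_{\mathrm{ATP}}|)$ at half the stall
force and half the maximal velocity. The bound time is a hypoexponential
sum of stages whose coefficient of variation falls as $1/\sqrt{n}$ for $n$
equal stages — a cascade of similar rates makes detachment timing more
deterministic and reduces the strain wasted at detachment. These formulas
are the package's independent oracle: at $\kappa/2 = 0.01\,g$ with
per-step forward drops of at least $5\,k_BT$, the stationary solver
reproduces them to well under 2%.

```{r soft-example}
m <- soft_limit_model(2, c(400, 1), t_off = 0.5, kappa = 0.5, g = 25)
soft_efficiency(m)
soft_operating_point(m)$v_opt_frac
```

## What the optimizations reproduce, and one open discrepancy

With two bound states at $-\Delta G_{\mathrm{ATP}}/k_BT = 25$ and
$\kappa/2 \le 40$, the free-velocity optimization lands at
$v^\* \approx 0.406$, $G_2 \approx -22.3\,k_BT$ and an attachment rate of
about 4.1 — matching the published optimum to three digits — with
$\eta^{\max} \approx 0.415$ and the stiffness at an interior optimum
($\kappa/2 \approx 32$) rather than at the cap. The published account
quotes 42% with the stiffness at 40; we find the efficiency surface nearly
flat between the two, and the 1% difference is within the tolerance we
claim. In the near-equilibrium limit the model reproduces
$\eta^{\max} \to 0.162$; with three bound states and a very high stiffness
cap the optimum climbs above 90%.

The fixed-force-stable scenario deserves a caution. Under our deterministic
reading of the stability constraint the optimizer discovers a high-stall
force family (fast attachment exchange, $\alpha_1 \approx 0$, stiffness at
the cap, stall force near $10\,k_BT/d$ per motor) that operates at
$\eta \approx 0.41$ with the constraint *inactive* — a monotone
force–velocity relation — above the published constrained value of 38%.
Thin-margin variants of such families (operating force only a few percent
below the deterministic stall) are illusory for finite ensembles: a
100-motor Gillespie run at such a load is dragged backward within a few
hundred time units, so the deterministic criterion is necessary but not
sufficient near the margin. A robustness requirement (a finite force
margin, or stability of the finite-$N_m$ dynamics) would be needed to
recover the stricter published figure; we report what the deterministic
criterion yields and expose the margin in the optimizer's constraint
diagnostics.

## Problem sizes used in the tests

The test suite runs the full pipeline at reduced multi-start counts (a few
to a couple of dozen starts depending on the dimension of the scenario) and
uses continuation to reach the high-stiffness and near-equilibrium optima;
these sizes reproduce the headline numbers stably under reseeding. The
stochastic comparisons use 50-motor ensembles over a few hundred time
units. Parameter-scan tables in the tests use coarse grids (4–6 points);
finer grids change the reported slopes only marginally.

## Known limitations

* Transient (time-dependent) solutions, length- or force-step protocols,
  and compliant filament backbones are out of scope.
* Discrete actin binding sites are neglected (heads bind anywhere); side
  branches of the cycle (e.g. detachment from the ADP state) are excluded.
* The stationary solver rejects lengthening ($v < 0$); the stochastic
  simulator does allow backward filament motion under super-stall loads,
  which is how instability manifests there.
* Efficiency at maximum power, power-density objectives, and global
  optimality certificates are not provided; the multi-start optimizer
  reports the best local optimum found, with per-start diagnostics.
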