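---
title: "An evolutionary game model of hospital co-opetition over EHR integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An evolutionary game model of hospital co-opetition over EHR integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrgame)
```

## The model

Two hospitals inside a medical consortium — a superior hospital A and a
subordinate hospital B, defined by referral direction, not size — repeatedly
choose between *cooperation* (sharing and using electronic health records,
EHR) and *competition* (withholding them). Both are boundedly rational: they
adjust strategies by imitation and payoff comparison, which is what
replicator dynamics formalise.

The payoff structure has five ingredients per hospital $i \in \{A, B\}$:
an original revenue $R_i$, an EHR stock $r_i$ (record-units), a value-added
benefit from using the partner's records
$\rho_i \mu_i \, r_{j} I$ (willingness $\rho_i$, ability $\mu_i$, unit
revenue $I$), a synergy term $\beta \rho_i \mu_i r_i I$ that only accrues
under mutual cooperation (complementarity $\beta$), an integration cost
$r_i C$, and a per-unit reward/penalty $H$: cooperators receive $r_i H$,
defectors pay $r_i H$. `payoff_table()` evaluates the four pure-strategy
profiles.

With $x$ and $y$ the probabilities that A and B cooperate, expectation over
the four profiles gives the two-population replicator system

$$\dot x = x(1-x)\left[r_A(2H - C) + y\,\beta\rho_A\mu_A r_A I\right],
\qquad
\dot y = y(1-y)\left[r_B(2H - C) + x\,\beta\rho_B\mu_B r_B I\right].$$

Two structural facts follow immediately and are enforced as tested
invariants: the boundaries of the unit square are invariant (each factor
$x(1-x)$, $y(1-y)$ vanishes there), and the original revenues $R_A$, $R_B$
cancel completely — a hospital's pre-existing turnover has no bearing on
whether integration takes off.

## Equilibria and regimes

The system always has the four corner rest points $O(0,0)$, $F(0,1)$,
$G(1,0)$, $K(1,1)$, plus an interior candidate

$$T = \left(\frac{C - 2H}{\beta\rho_B\mu_B I},\;
             \frac{C - 2H}{\beta\rho_A\mu_A I}\right),$$

admissible when both coordinates lie strictly in $(0,1)$. Note the
cross-subscripting: A's willingness and ability set the threshold on B's
axis and vice versa — each hospital's cooperation hurdle is determined by
how much the *other* side values its records. Stability is read off the
Jacobian: a rest point is an evolutionarily stable strategy (ESS) when
$\det J > 0$ and $\operatorname{tr} J < 0$, a saddle when $\det J < 0$.

The sign of $2H - C$ splits the parameter space (`classify_regime()`):

* **Subsidy-dominant** ($2H > C$): cooperation pays even unilaterally, $K$
  is the unique ESS and every interior start converges to mutual
  cooperation. Realisable in principle but fiscally demanding.
* **Cost-dominant bistable** ($2H < C$ with
  $\beta\rho_i\mu_i I > C - 2H$ for both hospitals): $O$ and $K$ are both
  ESS, $F$ and $G$ are unstable, and $T$ is an interior saddle whose stable
  manifolds separate the two basins. This is the empirically relevant case
  and the focus of the sensitivity analysis.
* **Cost-dominant invalid** (the synergy condition fails): no interior
  saddle; cooperation collapses from any start.
* **Boundary** ($2H = C$) as the degenerate separator.

```{r}
glance(analyze_game(baseline_params()))
```

## Basin geometry and sensitivities

In the bistable regime the probability of ending at mutual cooperation is
approximated by the area of the straight-edged quadrilateral
$F\,T\,G\,K$:

$$S_{FTGK} = 1 - \tfrac{1}{2}(x^* + y^*),$$

with closed-form partial derivatives: increasing in $\beta$, $\rho_i$,
$\mu_i$, $I$ and $H$, decreasing in $C$, and independent of $R_i$ and
$r_i$. `basin_sensitivity()` returns all eight derivatives; the identity
$\partial S/\partial H = -2\,\partial S/\partial C$ makes the
reward/punishment lever twice as effective, per unit, as a cost reduction.

The quadrilateral is a proxy: the true basin boundary is the saddle's
stable manifold, which is generally curved. `empirical_basin_fraction()`
integrates a lattice of initial conditions and measures the basin
numerically; the package asserts directional agreement between the proxy
and the measured fraction under single-parameter perturbations, not
equality. At the symmetric baseline the two agree closely (0.5 analytic
versus roughly 0.49 on a 9×9 lattice, the residual being lattice
discretisation at the separatrix).

## Baseline scenario and the sweep experiments

The reference scenario (`baseline_params()`) fixes $r_A = 800$,
$r_B = 500$, $\beta = 0.4$, $\rho_i = \mu_i = 0.5$, $I = 20$, $C = 5$,
$H = 2$, with starts at $x = y = 0.5$. It sits in the bistable regime with
the saddle exactly at $(0.5, 0.5)$ and $S_{FTGK} = 0.5$ — meaning the
printed initial condition coincides with the saddle, so the unperturbed
baseline is stationary by construction. This is documented behaviour, not
an error: the sweep experiments are informative precisely because varying
any one parameter moves the saddle off the start point, flipping the
outcome from all-compete to all-cooperate at an analytically predictable
value (e.g. the $\beta$-sweep flips at $\beta = 0.4$, where
$x^*(\beta) = 0.5$).

```{r}
sw <- sweep_parameter(baseline_params(), "beta", seq(0.1, 0.9, by = 0.1))
sw
attr(sw, "flip_interval")
```

`sweep_parameter()` varies $\rho$ and $\mu$ jointly across both players by
default, matching the experimental design of the simulation study;
per-player sweeps (`"rho_A"` etc.) are available. Sweeps export both the
phase-plane path and the time-course representation, since either reading
of the original figures is plausible.

## Numerical choices

* **Integrator.** `deSolve::lsodar` (adaptive, with root finding),
  `rtol = 1e-8`, `atol = 1e-10`, default horizon 50 time units; the
  integration stops early once
  $\max(|\dot x|, |\dot y|) < 10^{-10}$. Payoffs of order $10^3$ make the
  dynamics fast, so the horizon is generous. A dedicated test checks that
  tightening the tolerance does not change any terminal classification.
* **Clipping.** The exact flow preserves the unit square; states are
  clipped to $[0,1]^2$ only to absorb solver round-off, the largest clip
  is recorded on the trajectory, and tests bound it below $10^{-7}$.
* **Terminal classification** uses an absolute tolerance of $10^{-4}$
  against the corners; a trajectory that never leaves its (rest) starting
  point is `at_rest`, and anything else that is still moving at the
  horizon is reported `nonconverged` rather than guessed.
* **Zero tolerances.** Rest-point acceptance and det/tr sign calls are
  made relative to the payoff scale (entries of $J$ grow like
  $r_i \beta I$), with ties reported as `degenerate` — never silently
  promoted to ESS. The interior point must lie in
  $[10^{-9}, 1 - 10^{-9}]^2$ to avoid double-reporting a corner.
* **Sensitivities** are closed forms; tests require agreement with central
  finite differences to $10^{-6}$ relative tolerance on randomized
  bistable parameter sets.

## The scenario generator

`sample_scenarios()` draws parameter sets uniformly from ranges bracketing
the baseline by roughly an order of magnitude ($r_i \in [100, 1000]$,
$\beta \in [0.1, 0.9]$, $\rho_i, \mu_i \in [0.1, 1]$, $I \in [5, 50]$,
$C \in [1, 10]$, $H \in [0, 5]$) and keeps draws matching the requested
regime — seeded rejection sampling, bitwise reproducible, with an explicit
infeasibility error naming the binding constraint when the ranges cannot
produce the regime. $R_A$ and $R_B$ default to zero because no numeric
values are ever needed for them: their irrelevance is itself a tested
model property.

What the generator emulates is the *parameter uncertainty* of the model,
not real hospital finance: draws are independent and uniform, whereas real
consortiums have correlated stocks, costs and subsidy policies, and the
payoff model itself abstracts from repeated-game memory, more than two
parties, and stochastic (finite-population) dynamics. Passing tests
therefore certify the mathematical structure — equilibrium census,
stability pattern, basin monotonicity — under the stated assumptions, not
a calibrated forecast for any actual consortium.

## Problem sizes used in the checks

The shipped test-and-verification workloads use: 200 randomized bistable
sets for the sensitivity sign/finite-difference checks, 200 unconstrained
sets (5 states each) for the dual-route payoff identity, 100 for the
Jacobian cross-check, a 21×21 lattice for the subsidy-regime basin census,
and 9×9 lattices for basin-direction checks. These sizes keep the full
pipeline reproducible on a single CPU in well under a minute per check
while leaving the randomized coverage broad.

## Known limitations

* The quadrilateral area is an analytic proxy; for strongly asymmetric
  parameter sets the curved separatrix can deviate from the polyline
  noticeably, which is why the package never asserts equality between
  $S_{FTGK}$ and the empirical fraction.
* Exactly on the boundary $2H = C$ the interior point collapses onto the
  origin and the area statistic degenerates to 1; it is reported with
  `valid = FALSE` and a boundary flag.
* No Lyapunov or center-manifold analysis is attempted for degenerate
  (non-hyperbolic) rest points; they are labelled `degenerate`.
* The model covers two parties only; government, patients and platform
  integrators are outside its scope.
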