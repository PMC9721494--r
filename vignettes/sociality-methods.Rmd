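---
title: "Methods: contagion equilibria, replicator competition, and adaptive dynamics of sociality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contagion equilibria, replicator competition, and adaptive dynamics of sociality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociality)
```

## The model and its assumptions

The package studies a single continuous behavioral trait — the rate of social
interaction — under selection imposed by two contagions that both spread
through social contact. The *good* contagion confers a benefit while carried
(think useful information); the *bad* contagion imposes a cost (think
infectious disease). Four assumptions define the scope:

* **Independent SIS processes.** Each contagion follows
  susceptible–infectious–susceptible dynamics, and infection with one has no
  effect on susceptibility to the other. Cross-coupled or complex contagions
  (awareness–disease interactions, sigmoidal incidence) are out of scope.
* **Well-mixed contacts.** An individual's contacts are an unbiased sample of
  the population's contact pool, weighted by each type's interaction rate.
  There is no network, spatial, or assortative structure.
* **No demography.** Contagion dynamics are fast relative to births and
  deaths, so population composition changes only through strategy
  competition, never through mortality.
* **Timescale separation.** Contagion equilibration is fast relative to
  strategy competition, which is fast relative to change in the trait value
  itself. Each layer therefore sees the one below it at equilibrium.

Because the reproduction number of the good contagion,
$R^{(g)} = \sigma p_g/\gamma_g$, is proportional to the interaction rate
$\sigma$, the trait is parameterized throughout by $R^{(g)}$; the bad
contagion then has $R^{(b)} = cR^{(g)}$ with
$c = p_b\gamma_g/(p_g\gamma_b)$ its relative transmissibility.
`reproduction_numbers()` converts raw rates once at the boundary, and
`sociality_rates()` converts optima back — all comparisons (ESS versus
optimum) are invariant under this rescaling.

## Contagion equilibria

With time in recovery units, a monomorphic population obeys
$\dot I = R(1-I)I - I$ per contagion, with globally stable equilibrium
$\hat I = 1 - 1/R$ when $R > 1$ and extinction otherwise.
**Threshold convention:** at $R = 1$ exactly the extinct branch is returned.
This matters in practice: several interesting parameterizations (for example
a strategy at $R^{(g)} = 1/c$) put one contagion exactly at threshold, and
the extinct branch is the one consistent with the piecewise utility analysis
below. Dynamically, decay at threshold is algebraic ($\sim 1/t$), which is
why `simulate_mono()` cross-checks against the closed form rather than the
reverse.

For a population with a resident and a mutant strategy present at fractions
$1-f$ and $f$, each contagion's two prevalences are coupled only through the
probability $B$ that a random contact is infectious,
$$B = \frac{R_r(1-f)I_r + R_m f I_m}{R_r(1-f) + R_m f}.$$
At equilibrium each prevalence is slaved to $B$ via
$I_x = R_x B/(1 + R_x B)$, which reduces the per-contagion fixed-point
system exactly to one scalar equation $h(B) = 0$ on $(0,1)$, with $h$
strictly decreasing and $h(0) > 0$ precisely when the mixture's net
reproduction number
$R_{net} = \bigl(fR_m^2 + (1-f)R_r^2\bigr)/\bigl(fR_m + (1-f)R_r\bigr)$
exceeds 1. `dimorphic_equilibrium()` solves this by safeguarded bisection
(`uniroot`, interval $[0,1]$, tolerance $10^{-15}$) and checks the residual
of the full four-equation system afterwards ($<10^{-8}$). We chose this
reduction over a damped Newton iteration on the 2-variable system because it
is provably bracketed, cannot diverge, and algebraically reproduces the
rare-type closed forms in the $f \to 0$ limit. The theory guarantees the
endemic equilibrium of this two-group SIS system is unique and globally
attracting, so any convergent method finds the same point; a long-horizon
integration of the coupled ODEs (`method = "ode"`, horizon $10^4$ recovery
times, `lsoda` at `rtol = 1e-12`) is retained as an independent route and is
compared against the root solver in the test suite on randomized parameter
sets.

Solver outputs are clipped to $[0,1]$; inside the ODE right-hand side the
state is likewise clamped, because adaptive steppers can overshoot the
invariant box by more than roundoff during fast transients.

## Utility models

A utility model maps equilibrium exposure $(\hat I^{(g)}, \hat S^{(b)})$ to
payoff and must be strictly increasing in both arguments on the open unit
square — the package verifies this contract (positive partials, analytic
versus finite-difference agreement) rather than assuming it. Built-ins:

* **Cobb-Douglas** $(\hat I^{(g)})^\alpha(\hat S^{(b)})^{1-\alpha}$, the
  primary model. The weight $\alpha \in [0,1]$ measures emphasis on
  acquiring the good contagion versus avoiding the bad. We define
  $0^0 := 1$ so that $\alpha \in \{0,1\}$ degrade gracefully to
  single-objective utilities.
* **Linear** $\alpha \hat I^{(g)} + (1-\alpha)\hat S^{(b)}$. Not strictly
  concave; its social optimum can be unbounded.
* **CES** $(\alpha (\hat I^{(g)})^\rho + (1-\alpha)(\hat S^{(b)})^\rho)^{1/\rho}$
  with $\rho < 1$, $\rho \ne 0$. This standard two-good convention was
  chosen over weighted variants because it nests Cobb-Douglas in the
  $\rho \to 0$ limit, which the tests verify at $\rho = \pm 10^{-6}$.
  Near that limit the exponent $1/\rho$ amplifies roundoff by
  $O(1/\rho)$; quantities needing second derivatives (ESS curvature) are
  only numerically resolvable for moderate $\rho$, and the classifier
  reports "degenerate" rather than a sign extracted from noise.

`social_optimum()` maximizes the monomorphic utility over $R$ numerically.
The equilibrium map has kinks at $R = 1$ and $R = 1/c$, so a generic
optimizer can silently miss a kink optimum; instead the interior branch
$R > \max(1, 1/c)$ is optimized with `optimize()` (tolerance $10^{-10}$) and
compared against the explicit kink candidates, snapping to a kink when the
values tie within $10^{-12}$ (this is what returns the exact value 4, rather
than $4+\varepsilon$, when the optimum sits at $1/c$). If the utility is
still increasing at the right edge of the search interval the optimum is
reported as *unbounded-above* (`R_opt = Inf`) instead of a spurious finite
argmax. For Cobb-Douglas the closed form $\max(1/c, 1/(1-\alpha))$ is
recorded in the diagnostics and the numeric and analytic routes are
cross-checked in the tests.

## Replicator competition between two strategies

The mutant fraction follows $\dot f = f(1-f)\,[U_m(f) - U_r(f)]$ with both
utilities evaluated at the dimorphic contagion *equilibrium* for the current
$f$ — the quasi-static assumption. We deliberately never co-integrate the
contagion ODEs with the replicator equation: that would mix timescales the
model declares separated, and would make trajectories depend on arbitrary
contagion initial conditions.

Numerical choices: `lsodar` with `rtol = 1e-10`, stopping by root-finding
when $f$ comes within $10^{-6}$ of a boundary; default horizon
$t_{max} = 10^5$ (near-fixation dynamics can be slow — in the
$c = 4$ example below the utility gap shrinks to $\sim 5\times10^{-4}$ near
$f = 1$, giving fixation times of order $2\times10^4$); logarithmically
spaced output times so early fast transients and late slow approach are both
resolved.

Boundary outcomes are classified analytically rather than dynamically:
`classify_pairwise()` compares utilities at $f \to 0^+$ and $f \to 1^-$
using the rare-type closed forms, avoiding a $0/0$ ambiguity in the shared
contact term at exact boundaries. For Cobb-Douglas the log-utility
difference is strictly decreasing in $f$ (verified as a property test on
randomized instances), so the endpoint signs are decisive and bistability is
impossible; an interior sign change is refined by `uniroot` to $10^{-12}$.
Utility equality within $10^{-12}$ at both endpoints is reported as
degenerate, not silently classified. For non-Cobb-Douglas models a 51-point
scan guards against multiple roots and warns if it finds them.

The coexistence preset (`run_scenario(list(scenario = "fig3"))`: weight
$\alpha = 0.25$, $c = 0.25$, resident $R^{(g)} = 7$, mutant $R^{(g)} = 3$)
computes an interior equilibrium at $f_{eq} = 0.8187$, confirmed by both the
scalar-reduction and ODE-integration equilibrium routes; the mutant is
favored below, the resident above, making it globally attracting from any
interior composition.

## Adaptive dynamics

Invasion fitness is the log-utility advantage of a rare mutant,
$s_{R_r}(R_m) = \log U[R_m,R_r] - \log U[R_r,R_r]$, built from the
rare-mutant equilibrium closed forms. The selection gradient
$s'_{R_r}(R_r)$ has an exact piecewise Cobb-Douglas form, and a general
assembled form from the model's partials and the rare-mutant sensitivities;
the two are cross-checked against each other and against central finite
differences of the invasion fitness ($h = 10^{-6}$, agreement $10^{-6}$).
One derivation subtlety: the sensitivity of the mutant's bad-contagion
susceptibility to its own sociality is *negative* when the bad contagion is
endemic — the implementation carries the sign explicitly, and the
finite-difference oracle in the test suite pins it down.

Singular strategies: Cobb-Douglas uses the closed form
$\max(1, 1/c + \alpha/(1-\alpha))$, with the interior point infeasible
(gradient negative everywhere above threshold, collapse to $R = 1$) exactly
when $\alpha < 1/2$ and $c > (1-\alpha)/(1-2\alpha)$. General models use
bracket expansion (doubling, up to $R_{max} = 10^3$) plus `uniroot` on the
gradient. Classification uses standard second-order criteria: evolutionary
stability from the central second difference of invasion fitness in the
mutant trait at step $10^{-4}R^*$ (curvature within $10^{-8}$ of zero
reported as degenerate), convergence stability from the gradient's sign
change through $R^*$.

The dilemma comparison is structural: for any utility satisfying the
monotone contract, the gradient at the optimum has the sign of $1 - c$, so
the ESS over-socializes for $c < 1$, under-socializes for $c > 1$, and the
two coincide only at $c = 1$. Because that coincidence is structurally
unstable, it is classified as exact equality only within $|c-1| < 10^{-12}$,
and the regime classifier uses a dedicated label (`ESS_equals_opt`) for it
rather than forcing the boundary into one of the four generic regimes. The
boundary $c = 1-\alpha$ (where the optimum sits exactly at $1/c$ and the bad
contagion at its spread threshold) is assigned to the eliminated-at-optimum
regime, consistent with the threshold convention above.

## What the scenario presets emulate — and what they do not

The presets generate the package's own study conditions: parameter grids and
strategy pairs spanning both dilemma directions ($c \in \{0.25, 4\}$ around
a resident at the social optimum $R^{(g)} = 4$ with $\alpha = 0.75$; the
coexistence pair above; six pairwise-invasibility panels at
$c \in \{0.25, 1, 4\} \times \alpha \in \{0.25, 0.75\}$; regime and
ESS-versus-optimum maps). Two presets (`fig2` panels `A` and `A_alt`,
mutant $R^{(g)} = 5$ and $7$) cover two variants of the same qualitative
scenario; both show uniform mutant advantage. All presets are deterministic
and desk-scale (each runs in seconds on one CPU; the full test suite, with
its 1000-draw threshold sweep, 200-instance monotonicity property and
100-instance solver-versus-ODE comparisons, runs in well under a minute).

Passing these checks shows internal consistency of the three-timescale
machinery — closed forms against independent numerical routes — on an
idealized model. It does not validate the model against data: real
populations have contact structure, interacting contagions, finite-size
fluctuations, and demographic turnover, all of which are assumptions away.

## Known limitations

* Exactly two strategies compete at the intermediate timescale; polymorphic
  adaptive dynamics (evolutionary branching) are only visible indirectly,
  through mutual-invasibility regions of the PIP.
* Invasion analysis requires a resident with positive utility; for
  Cobb-Douglas this means $R_r > 1$, enforced as a precondition rather than
  assigning meaning to $\log 0$.
* The deterministic replicator equation has no drift: outcomes are decided
  by utility signs alone, however small the gap. Finite-population
  stochasticity (Moran/Wright–Fisher) is out of scope.
* CES second-order classification degrades near the Cobb-Douglas limit for
  the numerical reason given above; use the Cobb-Douglas model directly when
  $|\rho| < 10^{-3}$.
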