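# sociality

Social contact spreads useful things — information, innovations, foraging
knowledge — and harmful ones, above all infectious disease. `sociality` is an
R package for asking what level of social interaction evolves when both kinds
of contagion ride on the same contacts, and whether that evolved level is any
good for the population. It is aimed at theoretical ecologists and
evolutionary epidemiologists working with adaptive-dynamics or
evolutionary-game models of host behavior.

## The model

Two independent SIS contagions, a *good* one (g) and a *bad* one (b), spread
through a well-mixed population whose individuals interact at rate σ. With
per-contact transmission probabilities p_g, p_b and recovery rates γ_g, γ_b,
the contagions have basic reproduction numbers

    R⁽ᵍ⁾ = σ p_g / γ_g,   R⁽ᵇ⁾ = c R⁽ᵍ⁾,   c = (p_b γ_g) / (p_g γ_b),

so a single trait R⁽ᵍ⁾ (the *sociality strategy*) and the relative
transmissibility c summarize everything. Each contagion settles on its
globally stable equilibrium: prevalence `1 − 1/R` when `R > 1`, extinction
otherwise. Payoffs come from a utility U(Î⁽ᵍ⁾, Ŝ⁽ᵇ⁾) increasing in time spent
carrying the good contagion and in time spent free of the bad one — by
default the Cobb-Douglas family `U = (Î⁽ᵍ⁾)^α (Ŝ⁽ᵇ⁾)^(1−α)`, with linear and
CES alternatives behind the same interface.

The package analyses three nested timescales:

1. **Contagion (fast).** Closed-form monomorphic equilibria; the unique
   endemic equilibrium of the two-strategy (resident/mutant) system, solved
   by an exact scalar reduction with an ODE-integration cross-check; and the
   rare-mutant closed forms used by the invasion analysis.
2. **Competition (intermediate).** Replicator dynamics
   `df/dt = f(1−f)[U_m(f) − U_r(f)]` for the mutant fraction f, with
   utilities computed from the quasi-static contagion equilibrium at each f.
   Outcomes (mutant fixation, resident fixation, protected coexistence) are
   classified from the rare-type utility comparison at the two boundaries.
3. **Trait evolution (slow).** Invasion fitness
   `s_{R_r}(R_m) = log U[R_m, R_r] − log U[R_r, R_r]`, selection gradients,
   singular strategies with ESS/convergence-stability classification,
   pairwise invasibility plots, and the social-dilemma comparison. For
   Cobb-Douglas utility the closed forms are

        R_opt = max(1/c, 1/(1−α)),   R_ESS = max(1, 1/c + α/(1−α)),

   so the evolved level of sociality exceeds the collective optimum whenever
   the good contagion spreads more readily (c < 1), falls short of it when
   the bad contagion spreads more readily (c > 1), and can collapse to no
   sociality at all (R_ESS = 1) when avoidance dominates the utility.

## Worked example

```r
library(sociality)

# Good contagion four times as transmissible as the bad one (c = 0.25),
# utility weighted 3:1 toward acquiring the good contagion.
report <- social_dilemma_report(cobb_douglas_utility(0.75), c = 0.25)
print(report)
#> Social-dilemma regime: ESS_exceeds_opt_bad_eliminated_at_opt
#>   R_ESS = 7, R_opt = 4 (ESS_greater)
```

The socially optimal strategy (R⁽ᵍ⁾ = 4) holds the bad contagion exactly at
its spread threshold; the evolutionarily stable strategy (R⁽ᵍ⁾ = 7)
over-socializes, letting the bad contagion become endemic — everyone would be
better off at 4, but a population playing 4 is invadable:

```r
tr <- simulate_replicator(cobb_douglas_utility(0.75), R_r = 4, R_m = 7,
                          c = 0.25, f0 = 0.5)
print(tr)
#> Replicator trajectory: 140 time points
#>   terminal f = 0.999999 (mutant_fixed)
```

Strategies on opposite sides of the optimum can instead coexist at an
interior replicator equilibrium:

```r
out <- classify_pairwise(cobb_douglas_utility(0.25), R_r = 7, R_m = 3, c = 0.25)
print(out)
#> Pairwise competition outcome: COEXISTENCE
#>   interior equilibrium f_eq = 0.818671
#>   U_m - U_r at f=0: +1.150e-01; at f=1: -4.902e-02
```

Scenario presets (`run_scenario(list(scenario = "fig4"))`, …) export the
tables behind utility curves, two-strategy equilibria, pairwise invasibility
plots, the (c, α) regime map and the ESS-vs-optimum curves as CSV. A thin
command-line wrapper with the same functionality is installed under
`inst/cli/sociality`.

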