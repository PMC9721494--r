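Package: sociality
Title: Evolution of Social Interaction Rates Under Beneficial and Costly Contagion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how levels of sociality evolve when social
    contact spreads both a beneficial contagion (e.g. useful information) and a
    costly one (e.g. infectious disease), each following
    susceptible-infectious-susceptible (SIS) dynamics. The analysis proceeds on
    three nested timescales: fast contagion dynamics with closed-form endemic
    equilibria for monomorphic and two-strategy (resident/mutant) populations;
    intermediate replicator dynamics for the competition between two sociality
    strategies whose payoffs derive from quasi-static contagion equilibria; and
    slow adaptive dynamics yielding invasion fitness, selection gradients,
    singular strategies, pairwise invasibility plots, and the comparison of
    evolutionarily-stable with socially-optimal interaction levels, including
    classification of the resulting social-dilemma regimes. Cobb-Douglas,
    linear and constant-elasticity-of-substitution utility models are provided
    behind a common interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
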