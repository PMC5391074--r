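# smili

Agent-based simulation of self-governance in a small-scale fishery.

Many small-scale fisheries are governed informally by one of two archetypal
arrangements: **patron–client relationships (PCs)**, where a fishbuyer lends
fishers the daily cost of going fishing against delivery of the catch, and
**fishing co-operatives (co-ops)**, fixed-membership associations with shared
capital and collective trading.  `smili` simulates a community of 100
heterogeneous fishers, a shared fish stock, and an annual stream of new
buyers and co-ops, to study how micro-level trust — fishers' fixed
*reliability*, dynamically built *loyalty*, and co-op members' *initial
loyalty* (a history of working together) — determines which governance form
establishes, persists and dominates.  It is aimed at researchers in
social-ecological modelling and common-pool-resource governance.

## The model in brief

* **Stock** (Gordon–Schaefer): daily logistic update with linear harvest,
  `N' = max(0, N + rN(1 − N/K_t) − H)`, where each active fisher of skill
  `s` catches `q·s·N·f` (environmental factor `f`).  Regimes: deterministic;
  stochastic (shared unit-mean lognormal daily catch multiplier, cv 0.3);
  seasonal (`K_t = K(1 + 0.5·sin(2π·day/365))`).
* **Cheating**: with loyalty index `ℓ = L/(L+40)` and fresh uniforms α, β, a
  fisher cheats iff `reliability < α` and `ℓ < β`, i.e.
  `P(cheat) = (1 − reliability)(1 − ℓ)`; a cheater keeps the loan and sells
  at the beach price to a random other organization.
* **Loyalty**: +g per honest day for PC fishers (+g/2 in co-ops), −2g (−g in
  co-ops) per cheating day, floored at 0.  Buyers dismiss their least loyal
  members when over-supplied; co-ops expel loyalty-exhausted members.
* **Demography**: each year the richest inactive fisher founds a buyer (his
  capital plus a fixed endowment) with 5 random crew; a co-op of 5 random
  inactive fishers forms with an empty pot.  Buyers dissolve on negative
  capital; co-ops on negative aggregate capital (pot + member capital),
  exhausted loyalty, or fewer than 2 members.
* **Calibration** (closed form): `q = r/(2E)` puts the 50-fisher equilibrium
  at the MSY biomass `K/2`; `c = p·q·s̄·K/2` makes every organization's
  income exactly equal its expenses there.

The production engine is C++ (Rcpp); a pure-R reference engine consumes the
identical random-number stream, and the test suite asserts bit-identical
trajectories between the two.

## Worked example

```r
library(smili)
sim <- run_simulation(smili_preset("full_model"), seed = 7)
summary(sim)
#> Mean membership over the last 33 of 100 years:
#>   PC: 16.8   co-op: 24.4   inactive: 55.2   co-op share of members: 59.2%
#> Final biomass: 502.6 (K = 1000)
#> Mean age at dissolution by form and reason:
#>  kind  reason  n  mean_age max_age
#>  coop capital 95 0.9263158      23
#>    pc capital 97 1.1752577      26
#> Survivors at the end of the run:
#>  kind n mean_age max_age
#>  coop 5 73.80000      99
#>    pc 3 75.33333      97
```

Reading this: over the final 33 years of a century, 24.4 fishers on average
worked in co-ops and 16.8 in PCs (co-ops hold 59% of organized fishers at
the default initial loyalty of 40); the stock sits at the
maximum-sustainable-yield biomass K/2 = 500.  Most organizations of either
form fail within a year or two of entry for lack of capital — the fishery
only sustains ~50 active fishers, and yearly entry keeps it saturated — but
the co-ops that do establish persist for decades (one survivor is 99 years
old), giving their members long-term security that PCs do not match.

Other entry points:

```r
run_replicates(smili_preset("full_model"), replicates = 30, base_seed = 1)
run_validation_ladder(replicates = 30)
run_experiment(experiment_spec("loyalty",
                 list(initial_loyalty_mean = c(0, 10, 40, 100, 300))))
plot(sim)
```

A thin command-line front end is installed as `exec/smili`
(`smili run --preset full_model --years 100 --seed 7 --out dir/`; also
`validate`, `experiment --spec spec.yaml`, `calibrate`).

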