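---
title: "An agent-based model of self-governance in a small-scale fishery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of self-governance in a small-scale fishery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the model asks

Small-scale fisheries are often self-governed through one of two archetypal
arrangements: **patron–client relationships (PCs)**, in which a fishbuyer
lends each contracted fisher the daily cost of going fishing against delivery
of the catch, and **fishing co-operatives (co-ops)**, associations with fixed
membership, shared capital and collective trading.  Which form comes to
dominate a community is an emergent outcome of daily micro-level
interactions: lending, landing, trading — and cheating.  `smili` simulates a
stylized community of 100 fishers, a shared fish stock, and a yearly stream
of organizational start-ups, to study how three dimensions of trust shape
that outcome: fishers' fixed *reliability*, the dynamic *loyalty* built
between a fisher and their organization, and the *initial loyalty* of co-op
members (a proxy for a history of working together).

## Model structure

### Agents and organizations

Each fisher carries two immutable traits drawn at the start of a run —
reliability, clipped to $[0,1]$, and fishing skill, clipped at $0$ — and two
dynamic states: personal capital and loyalty toward their current
organization.  Loyalty is relationship-scoped: it starts at 0 with a new
buyer (or at the drawn "initial loyalty" for founding co-op members) and is
lost when the affiliation ends.  A fisher belongs to at most one
organization; unaffiliated ("inactive") fishers do not fish.

A PC is a star network around a buyer with its own capital, a fixed market
share (its daily fish demand), and a fixed subset of the population whose
reputation (reliability × skill) it knows.  A co-op is a fixed-membership
association; its operating account (the *pot*) starts empty and is fed by
daily membership fees and small capital contributions from wealthy members.
We track two co-op capital notions and never merge them silently: the pot
(operating account, reported in the census) and the association's aggregate
capital, pot plus the members' summed personal capital, which is the
quantity whose sign decides solvency — a co-op is its members' assets.

### The daily cycle

Every simulated day (365 days/year) executes, in fixed order:

1. **Crew selection** (buyers only): alternating rounds in which each
   under-supplied buyer signs the highest-reputation inactive fisher it
   knows, and a random inactive fisher approaches a random under-supplied
   buyer, until demand is covered or the pool is empty.  A buyer counts as
   under-supplied while the expected delivery of its crew at today's stock,
   $qN\sum_i s_i$, is below its market share — so at low abundance buyers
   take on more and more fishers, which is the mechanism that later traps
   them into lending without recovery.
2. **Loans**: every organization lends each member the day's fishing cost
   $c$; organization capital may go negative intra-day.
3. **Fishing**: each active fisher removes $q\,s_i\,N\,f_t$ biomass, capped
   proportionally so the day's harvest never exceeds $N$.
4. **Cheating decision**: with loyalty index
   $\ell = L/(L+h)$ and two fresh uniform draws $\alpha,\beta$, a fisher
   cheats iff $\text{reliability} < \alpha$ and $\ell < \beta$, i.e.
   $P(\text{cheat}) = (1-\text{reliability})(1-\ell)$.
5. **Trade**: honest PC fishers land with their buyer, who sells at the
   market price $p$, pays the beach price $\phi p$ and recovers the loan
   capped at the landing's beach value; honest co-op members receive the
   full market price, repay the loan (capped at the landing value), pay the
   membership fee, and contribute a fraction of capital above a threshold.
   A cheater keeps the loan and sells at the beach price to a uniformly
   random other organization, which books the trade margin.
6. **Loyalty update**: honest days add the form's growth rate ($g$ for PCs,
   $g/2$ for co-ops); cheating days subtract twice the form's growth rate,
   floored at 0.
7. **Renewal and expulsion**: over-supplied buyers dismiss their least loyal
   members (one average member's catch of tolerance, to avoid thrashing);
   co-op members whose loyalty is exhausted are expelled.
8. **Dissolution**: buyers with negative capital, and co-ops with negative
   aggregate capital, non-positive summed loyalty, or fewer than `min_size`
   members, go out of business (reported reason precedence:
   capital > loyalty > members).  Members become inactive; a dissolving
   co-op's positive pot is liquidated evenly to its members.
9. **Stock update** (below), then metrics are recorded.

On the first day of each year one new buyer — founded by the richest
inactive fisher, whose personal capital plus a fixed endowment becomes the
buyer's bankroll — and one new co-op of five random inactive fishers enter,
each receiving the fixed market share.  The founder is tracked as a
non-fishing *patron* so the population identity
(PC + co-op + patrons + inactive = 100) holds exactly; he returns to the
pool when his business folds.

### Fish stock and environments

The stock follows a daily Euler step of the Gordon–Schaefer logistic model
with linear harvest:
$$N_{t+1} = \max\!\big(0,\; N_t + r N_t (1 - N_t/K_t) - H_t\big),$$
with three regimes: *deterministic* ($K_t = K$); *stochastic*, a shared
unit-mean lognormal multiplier (cv 0.3) on all catch rates each day; and
*seasonal*, $K_t = K(1 + a\sin(2\pi\,\text{doy}/365))$ with amplitude
$a = 0.5$.  These functional forms are model choices of this package: for
the loyalty index, the environmental forcings and the crew-selection
mechanics only the qualitative behaviour is pinned down by the system being
modelled, so we use the simplest saturating, unit-mean and sinusoidal forms
and expose every constant as a configuration parameter.

## Calibration

`calibrate()` solves two conditions in closed form rather than by search.
With $E = 50 \times \bar s$ effort units (50 active fishers of mean skill
0.5), the harvested equilibrium $N^* = K(1 - qE/r)$ is set to the
maximum-sustainable-yield biomass $K/2$ by $q = r/(2E)$; total equilibrium
harvest then equals the MSY $rK/4$, which the market share splits evenly
over the ten reference organizations.  Break-even requires the value of a
mean fisher's equilibrium landing to equal the trip cost,
$c = p\,q\,\bar s\,K/2$: a buyer then nets
$(1-\phi)pY + \min(c, \phi p Y) - c = 0$ per honest fisher (the capped
repayment is what lets buyers run losses in scarcity), and a co-op's
aggregate nets zero, the fee being an internal member-to-pot transfer.  In
the *reference* preset (5 PCs, 5 co-ops, homogeneous fishers, no cheating,
no entry) the fishery therefore settles at $N = K/2$ with exactly 50 active
fishers — the calibration check.

Scale constants are arbitrary but fixed: $K = 1000$ biomass units,
$r = 0.04$/day (fast enough that the stock responds within a season, which
the seasonal regime requires), $p = 10$ per biomass unit, giving
$q = 8\times 10^{-4}$, $c = 2$ and market share 1 biomass/day.  Fishers
start with capital 20 (ten days of fishing cost); new buyers receive an
endowment of 100 (five members' starting capital) on top of the founder's
wealth, while new co-ops start with an empty pot — entrants' asymmetry in
the direction observed for real fishbuyers.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `loyalty_growth` g | 1 /honest day | PC loyalty gain; co-ops gain g/2 |
| `loyalty_decay` d | 2g | loss per cheating day, scaled to the form's own rate |
| `loyalty_half_saturation` h | 40 | loyalty at which the cheat-relevant index reaches 0.5 |
| `beach_price_fraction` φ | 0.7 | buyer margin 30%; also the cheater's side-sale price |
| `membership_fee` | 0.1 c | daily co-op fee into the pot |
| `contribution_rate` / `capital_threshold` | 5e-6 / 200 | capital sharing by wealthy members |
| `known_fraction` | 0.5 | share of the population a buyer can recruit by reputation |
| `min_size` | 2 | smallest viable co-op |
| `stochastic_cv`, `seasonal_amplitude` | 0.3, 0.5 | environmental forcing strength |

Two interpretation choices deserve emphasis.  First, the **cheating rule**:
the conventional statement of the rule ("a fisher will cheat if
reliability > α and loyindex < β") read literally makes the most reliable
fishers cheat the most, inverting what reliability means; the default rule
inverts the reliability gate so that trustworthy fishers cheat least, and
the literal variant is retained as `cheat_rule_variant = "as_printed"` for
auditing.  Note the consequence: with homogeneous reliability 1.0 — the
validation-ladder setting — the default rule produces *no* cheating at all
(and the literal rule produces *certain, permanent* cheating from
loyalty 0), so ladder rungs that differ only in the co-op loyalty growth
rate produce identical event streams and the expected rung-(iii) reversal
(PC dominance driven by loyalty-starved co-ops) cannot occur under either
variant.  We report this as a known limitation rather than engineering
around it.  Second, the **decay scaling**:
decay is twice each form's own growth rate, so both forms erode loyalty at
the same multiple of the speed they build it and the co-op handicap is
purely one of speed.  A global decay constant (twice the PC rate for
everyone) was implemented and rejected: it imposes a fourfold
decay-to-growth penalty on co-ops that makes co-op loyalty collapse below
loyalty ≈ 30 under all conditions, erasing the viability of low-loyalty
co-ops in homogeneous communities that the model is meant to exhibit.

## What the simulations show (and do not)

At the defaults, the package's own experiments reproduce the qualitative
structure of the system: the calibrated reference sustains exactly 50
fishers at $N = K/2$ for a century; co-op share of organized fishers rises
monotonically with initial loyalty (≈27% at loyalty 0 to ≈54% at 300, with
parity of ≈24 fishers per form at loyalty 40); at low initial loyalty most
entering co-ops dissolve within their first year while established co-ops
persist to the end of the century, which no PC ever does.  Quantities
computed by `scripts/acceptance.R` at 10–30 replicates: reference activity
50.0 fishers; co-op membership 23.8 at initial loyalty N(40, 5); co-op share
41% (deterministic) and 39% (seasonal) in the low-loyalty,
low-heterogeneity corner.

Three expected behaviours do **not** emerge under our functional forms, and
we leave them visibly unmet rather than tune for them: the co-op share in
the low-loyalty/low-heterogeneity corner stays ≈20 points below its
expected level (≈60%) and the seasonal regime does not reliably raise it
(≈71% expected); the co-op share
is mildly *increasing* in reliability heterogeneity (buyers' targeted
recruitment keeps their crews more reliable than co-op survivors, inverting
the expected selection contrast); and the ladder reversal discussed above.
All three trace to the freely chosen functional details (the exact
loyalty-index and crew-selection equations and the environmental forcing
forms), for which we substituted the simplest behaviour-compatible choices.

## Numerical and reproducibility choices

* One global R random stream per run, consumed in a documented fixed order
  (see `R/engine_r.R`); replicate $i$ of an experiment uses seed
  `base_seed + i - 1`.  The compiled engine mirrors the pure-R reference
  implementation operation for operation — including long-double
  accumulation where R's `sum()` uses it — and the test suite asserts
  bit-identical trajectories between the two across presets.
* Ties break deterministically toward the lowest id (recruitment,
  dismissal, founder selection).
* Sampling without replacement uses a partial Fisher–Yates shuffle with one
  uniform draw per pick, identical in both engines.
* Money is conserved exactly: cash enters only via fish sales and entry
  endowments, leaves only as sunk daily fishing costs and dissolution
  write-offs; the per-day ledger identity is asserted to 1e-8 over full-year
  traces.
* Degenerate inputs are defined, not special-cased: sd 0 distributions are
  point masses; a zero stock yields zero catches; a cheater with no other
  organization sells to the external market at the beach price; an
  organization may run arbitrarily negative within a day and is judged only
  at day's end.

### Problem sizes

Simulations are 100 years × 365 days (36500 steps) with 100 fishers — long
enough for the membership patterns to become quasi-stable.  The package's
experiment defaults use 30 replicates, with the replicate count a plain
argument for anyone wanting publication-scale repetition (hundreds to
thousands): the reported trends are means over replicates and stabilize far
below such counts, and 30 replicates keep a full experiment grid in the tens
of seconds on one core.  The test suite uses
2–15-year runs for mechanism checks and 5–12 replicates for system-level
checks; `scripts/acceptance.R` uses 10 replicates for the reference
scenario and 30 elsewhere.

## What the generator emulates — and what it leaves out

The synthetic community emulates: trait heterogeneity (clipped normal
reliability and skill), trust accumulation and erosion with the cheating
feedback, demand-driven crew churn, annual organizational entry, scarcity
from over-entry, and environmental variability in two canonical forms.  It
deliberately omits — matching the study's scope — price dynamics and
fluctuating demand, government involvement and subsidies, livelihood
diversification, long-term resource management by the agents, spatial
structure, multi-species dynamics, and any demographic turnover of the
fisher pool.  Passing tests therefore say nothing about fisheries where
prices move, co-ops diversify, or entry is policy-driven; the model is a
laboratory for the trust mechanisms, not a forecasting tool.
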