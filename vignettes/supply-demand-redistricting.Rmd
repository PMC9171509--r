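---
title: "Supply/demand-ratio redistricting of organ allocation units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supply/demand-ratio redistricting of organ allocation units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungalloc)
```

## The problem

In a tiered organ allocation system, a graft recovered at an organ
procurement centre (OPC) is first offered to the lung transplant centre
(LTC) whose *local allocation unit* contains that OPC, and only later shared
regionally or nationally. When the units are historical accidents — in the
French setting their sizes ranged from 1 to 32 OPCs across nine centres —
centres with large units receive far more offers per listed candidate than
centres with small ones, independently of their actual demand.

`lungalloc` implements the redistricting method behind France's 2020 lung
allocation reform, on synthetic geographies: redraw the units so that every
centre's **supply/demand ratio**

$$ r_\ell \;=\; \frac{\text{lungs recovered and transplanted from the unit of } \ell}
                 {\text{all transplants performed at } \ell} $$

is close to a common target (0.5: each centre sources about half its demand
locally, the rest through national sharing), subject to proximity (every
member OPC within a 2-hour drive of its LTC, inclusive) and unit-size
constraints (5 to 15 OPCs). Judged across centres, a good map has similar
ratios and a small standard deviation of $r_\ell$.

## The search

With $n$ OPCs and $m$ LTCs the unconstrained space holds $(m+1)^n$
assignments (each OPC joins one unit or none) — $10^{183}$ at the national
scale, which `search_space_size()` reports in exact arithmetic. The
implementation therefore works in two stages:

1. **Per-centre enumeration** (`enumerate_feasible_units()`): all subsets of
   the travel-eligible pool are enumerated by a depth-first scan over the
   pool sorted by supply descending, pruning any branch whose running supply
   already exceeds the upper ratio band or whose best possible completion
   cannot reach the lower band (`pruned_subset_iterator()`). The yield is
   provably identical to the naive powerset filter, which the test suite
   checks by exhaustion on small pools. Results are ranked by distance to
   the target ratio, then total travel time, then lexicographic member
   tuple, and capped at `shortlist_k` (default 200; truncation is flagged
   because the global stage is then only optimal over the shortlists).

2. **Joint assignment** (`solve_assignment()`): one unit per centre, units
   pairwise disjoint, minimizing the *population* standard deviation of the
   ratios over the fixed set of centres (a complete enumeration of the units
   being scored, not a sample). The search is an exact depth-first
   branch-and-bound with three ingredients:

   * a *fast path*: since $\mathrm{Var}(x) = \min_\mu \frac1n \sum (x_i -
     \mu)^2$, the unconstrained minimum over per-centre ratio choices
     separates given $\mu$; scanning $\mu$ over breakpoint intervals yields
     the exact unconstrained optimum, and when its selection happens to be
     conflict-free it is the global optimum;
   * a per-node lower bound from the same scan restricted to the remaining
     shortlists, plus a travel-bound prune on sd plateaus;
   * a node budget (`search_budget`, default 5e5). Small instances — in
     particular everything the oracle-equivalence tests cover — are solved
     exactly well inside it; if a large instance exhausts the budget the
     best assignment found is returned with `certified = FALSE` and a
     warning, the usual behaviour of resource-capped branch-and-bound
     solvers.

**Empty units.** A centre whose pool cannot reach the ratio band gets the
empty unit (ratio 0) and a flag rather than aborting. When disjointness
conflicts make a full assignment impossible, `optimize_units()` also allows
the empty unit as a *last resort*, minimizing the number of empty units
lexicographically before the sd. This ordering matters: the sd alone is
minimized by the degenerate all-empty map (every ratio 0, sd 0), which no
allocation authority would accept. Plain `solve_assignment()` keeps the
specified strict behaviour and raises an infeasibility error naming the
smallest conflicting centre pair.

**Locked members.** Centres that insisted on keeping established OPC
collaborations are modelled by `locked` sets that every candidate unit must
contain. By default locked members count towards the size screen;
`lock_size_exempt = TRUE` exempts them.

## The offer simulator

`run_simulation()` streams grafts through the tiered cascade of either
scheme: *previous* (local unit, then other same-region LTCs, then all
remaining LTCs nationally) or *new* (local, then directly national —
the regional tier is removed, and unassigned OPCs offer straight to the
national tier). A configurable fraction of grafts (default 0.15) bypasses
geography on a national high-urgency tier. Acceptance is a per-centre
Bernoulli (default 0.4, inside the reported 34–85% per-centre discard
range); candidate-level selection inside a centre is deliberately not
modelled. The national queueing rule is not public; the default is a
round-robin rotation over centres (advancing per graft that reaches a
national tier), with a random order as the alternative. Shipping distance
is straight-line kilometres between source OPC and recipient LTC, and cold
ischemia is an affine proxy of shipping minutes (intercept 240 min, slope
1) — a labelled stand-in, not a clinical model.

## Outcome estimators

Waitlist outcomes are competing risks: transplantation versus death or
delisting for clinical worsening. `cumulative_incidence()` implements the
non-parametric Aalen–Johansen estimator
$\mathrm{CIF}_k(t) = \sum_{t_i \le t} S(t_i^-)\, d_{k,i}/n_i$, whose
decomposition conserves probability ($\sum_k \mathrm{CIF}_k + S = 1$ at
every event time); `kaplan_meier()` is the product-limit estimator for
post-transplant survival. Ties between events and censorings resolve events
first (the standard convention). Point estimates only; variance and
confidence intervals are out of scope, as is Fine–Gray *regression* — the
quantities reported in this setting are cumulative incidence curves, which
the Aalen–Johansen estimator is.

## The synthetic world

Real procurement and transplant activity sits in a legally restricted
national registry, so all experiments run on `generate_scenario()`
geographies. Defaults state the reference setting:

| parameter | default | why |
|---|---|---|
| `n_opc`, `n_ltc` | 183, 9 | the national centre counts |
| `field_km` | 1000 | metropolitan-France scale, square field |
| `speed_kmh` | 70 | mean driving speed for the travel matrix |
| `mean_lungs_per_opc` | 12 | ≈ 2 grafts/OPC/year over a six-year window, matching ≈ 370 transplants/year nationally |
| `procurement_dispersion` | 1 | gamma shape; strong regional heterogeneity of recovery |
| `demand_range` | 150–350 | transplants per LTC over the window (≈ national supply/demand closure) |
| `candidates_per_graft_range` | 1.0–1.6 | around the observed 1.1 candidates per graft |

OPC and LTC coordinates are uniform on the field; per-OPC supply is
Poisson with gamma-distributed intensity; per-LTC demand is drawn
independently of local supply (that independence *is* the disparity the
method corrects; `supply_demand_coupling` exists for sensitivity runs). The
"historical" map assigns each of nine centres its published unit size
(1–32 OPCs, nearest available OPCs first), reproducing the size skew the
reform replaced; at other centre counts the sizes are resampled from that
set and rescaled.

What the generator does **not** emulate: population-density clustering of
OPCs (uniform placement makes travel-eligible pools thinner than around
real conurbations, so at full scale some synthetic centres legitimately
cannot reach the 0.4–0.6 band and end up with empty units), road-network
topology, blood-group matching, and any behavioural response of centres. A
green equity test therefore establishes that *the optimizer reduces
ratio/offer dispersion relative to a size-skewed status quo in worlds with
the stated structure* — not that it reproduces the real French map.

## Scale of the test worlds

The multi-replicate properties (50 seeded scenarios) run on a scaled world:
60 OPCs, the same nine centres with the same skewed historical sizes, a
600 km field (keeping eligible pools at realistic ~10–14 OPCs), and demand
55–110 so national supply ≈ demand still holds. This is purely a runtime
measure — full-scale enumeration 50 times would take hours — and the scale
was fixed before measuring outcomes. Equivalently scaled optimizer settings
(`shortlist_k = 25`, `search_budget = 2000`) keep each replicate under a
few seconds; the equity contrast is so large (ratio-sd ≈ 0.15–0.25
optimized vs ≈ 0.6–1.0 historical) that certification of per-replicate
optimality is irrelevant to the conclusion.

## Numerical choices

* The 2-hour travel screen is inclusive (≤ 120 min).
* Ratio-band tolerance defaults to 0.1 around the 0.5 target, bracketing
  the 0.29–0.6 spread observed in the reference model-1 design.
* Dispersion summaries expose the sd convention: the pre-change disparity
  figures reproduce under the sample (n−1) convention, the post-change
  offers-per-candidate sds under the population convention; neither is
  hidden behind a default silently.
* Tie-breaks everywhere are deterministic (travel time, then lexicographic
  member tuples), so permuting input row order never changes the result.
* Synthetic travel noise is truncated at zero; matrices are directed
  OPC→LTC; coordinates are planar km (project before use, `great-circle`
  geodesy is out of scope).

## A worked example

```{r example, eval = FALSE}
scen <- generate_scenario(
  scenario_config(n_opc = 60, n_ltc = 9, field_km = 600,
                  demand_range = c(55, 110), seed = 42))
fit <- optimize_units(scen$centres, scen$matrix, scen$activity,
                      optimizer_config(shortlist_k = 25,
                                       search_budget = 2000))
fit$profile                                   # optimized ratios
ratio_profile(scen$historical_map, scen$activity)  # skewed status quo
```

## Known limitations

* The joint stage is exact only over the per-centre shortlists and within
  the node budget; both caps are reported (`shortlist_truncated`,
  `certified`).
* The offer simulator has no candidate-level queue, so per-candidate
  outcomes (e.g. waitlist mortality by centre) are outside its reach.
* Real travel-time matrices must be supplied by the caller; the synthetic
  matrix is straight-line distance at constant speed plus noise.
* The published model-ratio tables and real shipping distances cannot be
  reproduced without the restricted registry; they are covered only
  qualitatively by the equity properties.
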