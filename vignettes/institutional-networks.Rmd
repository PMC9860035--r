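---
title: "Institutional networks of monitoring and punishment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Institutional networks of monitoring and punishment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopnet)
library(dplyr)
```

## The model

`coopnet` studies how a group of `N` individuals can sustain cooperation in a
linear public goods game when cooperation is enforced through an
*institutional network*: a simple directed graph in which a link `i -> j`
makes individual `i` responsible for monitoring individual `j` and punishing
`j` if `j` does not contribute. The same game played on different networks
yields organizations ranging from fully distributed (everyone watches
everyone, punishment is collective) to strictly hierarchical
(command-and-control out-trees), and the package's purpose is to map which
structures are socially optimal under which costs of monitoring and
punishment.

Six scalar parameters govern the game (`game_params()`):

| parameter | meaning | default in the demos |
|---|---|---|
| `N` | group size | 6 or 12 |
| `b` | public-goods efficiency: contributions are multiplied by `b >= 1` and shared equally among the *other* `N - 1` members | 2 |
| `m` | monitoring efficiency: monitoring one individual costs `1/m` | varies on the sweep grid |
| `p` | punishment efficiency: one unit spent punishing removes `p` units from the target | varies on the sweep grid |
| `c_t` | contribution threshold, the total amount a contributor pays (resource units) | 1 |
| `c_p` | punishment reserve held by anyone with monitoring duties, `0 < c_p <= c_t` | 0.2 |

At a Nash equilibrium only two strategies can occur: the **threshold
contributor**, who pays exactly `c_t` split across monitoring
(`k_out / m`), the punishment reserve, and the public good; and the **pure
free-rider**, who pays nothing and absorbs punishment. A contributor's
reserve is split equally over the free-riders they monitor and is donated to
the public good when there are none. Free-riding monitors never punish.
These allocation rules are deterministic, so `compute_payoffs()` is exact
arithmetic:

```{r payoffs}
pars <- game_params(N = 3, b = 2, m = 4, p = 3, c_t = 1, c_p = 0.25)
motif <- institution(data.frame(source = c(1, 1), target = c(2, 3)), n = 3)
tidy(compute_payoffs(motif, all_contributors(3), pars))
```

## Equilibrium and feasibility conditions

Three analytic conditions characterize when universal contribution is both
socially efficient and a Nash equilibrium:

1. **Efficiency.** Group payoff under universal contribution is
   `b (N c_t - K/m) - N c_t`, positive exactly when
   `b > N c_t / (N c_t - K/m)` (`efficiency_condition()`).
2. **Minimum in-degree.** Free-riding saves `c_t` but costs
   `p c_p + b c_p / (N-1)` per punisher (the damage plus the punisher's
   redirected reserve), so each node needs at least
   `ceil( c_t / (c_p (p + b/(N-1))) )` monitors (`min_in_degree()`).
3. **Maximum out-degree** (span of control). Monitoring `k` others costs
   `k/m` and must leave room for the reserve under the threshold:
   `floor( m (c_t - c_p) )` (`max_out_degree()`).

Networks exist only when the span of control covers the required in-degree,
and the socially optimal ones minimize links: `K = N * min_in`, with the
out-links concentrated on as few monitors as possible so that the number of
*pure contributors* (out-degree-0 nodes) is maximized.

`is_nash()` verifies these conditions numerically: it tests every node's
pure label switch and, as a safety net for the analytic result that only the
two pure strategies survive, a uniform grid of partial contributions in
`[0, c_t]` (default 21 points; a partial payer allocates monitoring first,
then the reserve, then the public good, and is punishable as a free-rider).
The grid is a heuristic check, not a proof — 21 points is enough to catch
any coding error in the allocation priorities while keeping the check
`O(N * grid)` payoff evaluations. Deviations must be *strictly* profitable
(tolerance `1e-9`) to refute an equilibrium, the standard weak-preference
convention. `brute_force_socially_efficient_nash()` enumerates all `2^N`
pure-strategy profiles (guarded at `N <= 12`) and returns the
payoff-maximal Nash profile, breaking ties toward universal contribution.

A caution established while testing: the claim that the socially efficient
Nash profile is uniform (all contribute or all free-ride) holds on *socially
efficient structures* — connected minimal-link networks with in-degree
exactly `min_in` — where a free-rider cluster must be closed under
in-neighbourhood and therefore spreads to the whole group. It is **not**
true on arbitrary networks satisfying the degree bounds: with surplus
monitoring links, two heavily loaded monitors watching only each other can
free-ride stably, and that mixed equilibrium can dominate universal
contribution because their monitoring spend is almost pure waste. The
package's tests assert uniformity only on the optimal family.

## Measuring hierarchy

Four measures, each in `[0, 1]`, quantify how hierarchical a directed
network is; all four equal 1 exactly for an out-tree.

* **Connectedness**: 1 minus the fraction of node pairs in different weak
  components.
* **Graph hierarchy `H`**: 1 minus the fraction of reciprocally linked
  pairs among linked pairs, where "linked" means a directed path runs in at
  least one direction. Out-trees score 1, the complete digraph 0.
* **Graph efficiency `E`**: 1 minus the proportion of surplus links beyond
  the `N - 1` needed for a single component,
  `E = 1 - (K - (N-1)) / (N(N-1) - (N-1))`; the "maximum possible links"
  denominator is the full digraph `N(N-1)`, anchored by the requirement
  that a completely connected network scores 0. Single-component networks
  only.
* **Least upper boundedness**: 1 minus the fraction of pairs lacking a
  common ancestor, against the worst case `(N-1)(N-2)/2`. Two denominator
  conventions circulate in the literature; every network this package
  generates scores exactly 1, so the choice is inert here and the simpler
  worst-case count is used.

The **composite score** is `E * H`: 0 for the fully distributed complete
graph, 1 for an out-tree. One consequence of computing `H` on reachability
deserves a note, because it is easy to get wrong by hand: in a star whose
root is monitored back by one child (the optimal tree-like structure at
`min_in = 1`), leaf pairs are *not* linked — no path runs between siblings —
so for `N = 6` there are 9 linked pairs, one reciprocal, and `H = 8/9`, not
`14/15`:

```{r star}
krackhardt_scores(build_rooted_tree_with_reciprocal(6, 5))
```

For the optimal family, `E` depends on `(N, d_in)` alone:
`E = 1 - (N d_in - (N-1)) / (N-1)^2`, which is why graph efficiency rises
with punishment efficiency (cheaper punishment means fewer required
monitors, hence fewer links).

## Sampling socially optimal networks

`optimal_network_spec(N, d_in, d_out_cap)` describes the family: in-degree
exactly `d_in` everywhere, out-degrees at most the cap (clamped to `N - 1`),
`K = N * d_in`, and `ceiling(N * d_in / cap)` monitors so pure contributors
are maximized. `sample_optimal()` draws from it:

1. choose the monitor set uniformly at random;
2. draw the monitors' out-degrees as a uniform random composition of
   `N * d_in` with parts in `[1, cap]` (exact dynamic-programming counts);
3. give each monitor its targets sequentially, sampling without replacement
   with probability proportional to the targets' remaining in-capacity —
   stub matching conditioned on never creating a self-loop or parallel
   link;
4. reject and retry draws that dead-end or come out weakly disconnected
   (cap: 10,000 attempts per sample).

Step 3 is the one genuinely open design choice. Pure
permute-all-stubs-then-reject sampling is unusable at the dense end of the
family: for `N = 6, d_in = 5`, where the only member is the complete graph,
the chance that a random stub permutation is simple is about `1e-5`, so
conditioning the draw on simplicity arc by arc (which is exact for that
forced case and near-uniform elsewhere) was adopted instead. Exact uniform
sampling over connected degree-constrained digraphs is a hard problem; what
the downstream results need is the constraint set itself, which every
accepted draw satisfies, plus determinism, which the seed argument
provides without touching the caller's RNG state.

```{r sampler}
spec <- optimal_network_spec(12, d_in = 1, d_out_cap = 3)
spec
nets <- sample_optimal(spec, 3, seed = 1)
sapply(nets, function(g) length(pure_contributors(g)))
```

## The efficiency sweep

`run_sweep()` maps the (m, p) plane. For each cell it computes the degree
constraints, gates on feasibility (in infeasible cells universal
free-riding is the socially optimal equilibrium), samples the optimal
family, and records `E` (constant per cell), the min/median/max of `H`, the
median composite, and the median-`H` network as the cell's representative.

The demo grids were fixed once from the constraint structure for
`N = 6, b = 2, c_t = 1, c_p = 0.2`: punishment efficiencies
`(0.6, 0.85, 1.3, 2.1, 4.6)` hit `min_in = 5, 4, 3, 2, 1` and monitoring
efficiencies `(2.5, 3.75, 5, 6.25, 20)` hit spans of control
`2, 3, 4, 5, 15` (the last clamped to 5), so the grid spans the full range
from the completely distributed to the maximally hierarchical regime. With
`b = 2`, cells needing many links also fail the efficiency condition at low
`m` — that is the model speaking, not a tuning choice: monitoring thirty
links is simply too expensive unless monitoring is very cheap.

```{r sweep}
base <- game_params(N = 6, b = 2, m = 1, p = 1, c_t = 1, c_p = 0.2)
sw <- run_sweep(base,
  m_grid = c(2.5, 3.75, 5, 6.25, 20),
  p_grid = c(0.6, 0.85, 1.3, 2.1, 4.6),
  n_samples = 200, seed = 42
)
sw |>
  filter(feasible) |>
  select(m, p, min_in, out_cap, E, H_median, composite_median)
```

Reading the result: at high `m` and low `p` (top left of the feasible
region) the only optimal network is the complete graph — distributed
monitoring, collective punishment, composite 0. As punishment gets more
efficient, `min_in` falls, links get scarcer, and optimal networks become
tree-like; at `min_in = 1` they are stars/trees with a single reciprocal
link back to the root and composite scores above 0.85. The special corner
`min_in = max_out = 1`, where the only optimal network is the directed
cycle (composite 0 despite maximal sparsity), requires `b > 5` at these
settings and so does not appear on the demo grid; `build_cycle()` covers it
directly. `autoplot(sw)` draws the composite heat map.

## Problem sizes, determinism, degenerate inputs

* Demonstration and test runs use 200–10,000 samples per cell and `N` of 6
  or 12. The median-`H` statistic stabilizes at a few hundred samples for
  these sizes because the optimal families are small; larger runs change
  nothing but the tails. A 120-node draw works through the same code path.
* All sampling is reproducible: `sample_optimal()` and `run_sweep()` take a
  seed and derive per-cell sub-seeds; re-running a sweep with the same seed
  reproduces the CSV byte for byte.
* Exact-boundary arithmetic: the in-degree ceiling and out-degree floor are
  taken on the exact rational value with a `1e-9` guard, so
  `c_t / (c_p (p + b/(N-1))) = 2` gives `min_in = 2` rather than spilling
  to 3 through floating-point noise. Payoff comparisons use absolute
  tolerance `1e-9`.
* Degenerate inputs fail loudly: a contributor whose role costs more than
  `c_t` raises a classed error naming the node; hierarchy is undefined (an
  error) on link-free graphs; efficiency and least upper boundedness reject
  multi-component networks; `optimal_network_spec()` rejects
  `d_out_cap < d_in`.

## What the generator does and does not emulate

The sampled networks realize the model's own idealizations: binary
monitoring links, a common threshold for all individuals, perfectly
informative monitoring, and simultaneous one-shot play. Passing tests show
the game arithmetic, the analytic conditions, and the structural claims are
internally consistent — they say nothing about noisy monitoring, dynamic
network formation, heterogeneous thresholds, robustness to shocks, or
second-order free-riding by contributors who shirk punishment duties, all
of which are outside the model. The hierarchy scores are purely structural:
two organizations with identical graphs but different real-world authority
relations score identically.
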