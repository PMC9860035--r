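# coopnet

Socially optimal monitoring-and-punishment networks for public goods games.

## The problem

Groups sustain cooperation by monitoring members and punishing free-riders,
but monitoring and punishing are themselves costly. Who should watch whom?
`coopnet` implements a game-theoretic model in which the answer is a
*directed network*: a link `i -> j` makes individual `i` responsible for
monitoring `j` and punishing `j` if `j` fails to contribute to a public
good. Depending on how costly monitoring and punishment are, the socially
optimal network ranges from fully **distributed** (the complete digraph:
everyone watches everyone, punishment is collective) to strictly
**hierarchical** (sparse out-trees: a few monitors carry all enforcement
duties while everyone else contributes in full).

The package provides:

- exact payoff computation for the public goods game on any directed
  network (`compute_payoffs()`, with `tidy()`/`glance()` methods);
- the analytic equilibrium and feasibility conditions, and brute-force
  verification of them (`degree_constraints()`, `is_nash()`,
  `brute_force_socially_efficient_nash()`);
- construction and random sampling of socially optimal degree-constrained
  networks (`build_out_tree()`, `build_complete()`, `build_cycle()`,
  `optimal_network_spec()`, `sample_optimal()`);
- Krackhardt-style structural hierarchy measures — connectedness, graph
  hierarchy, graph efficiency, least upper boundedness — and a composite
  score (`krackhardt_scores()`);
- parameter sweeps over the monitoring/punishment efficiency plane with a
  ggplot2 heat map (`run_sweep()`, `autoplot()`), plus readers/writers for
  networks (edge-list CSV, GraphML), parameters (JSON/YAML), and sweeps.

Tables go in and out as tibbles; networks are `igraph` objects.

## The model in brief

`N` individuals play a one-shot linear public goods game. Contributions are
multiplied by an efficiency factor `b` and shared equally among the *other*
`N - 1` members. A **contributor** pays exactly the threshold `c_t`, split
in priority order across monitoring duties (each outgoing link costs
`1/m`), a punishment reserve `c_p` (spent `c_p/F` on each of their `F`
free-riding monitorees, donated to the public good when `F = 0`), and the
public good. A **free-rider** pays nothing and loses `p` per unit spent
punishing them; free-riding monitors never punish. Under universal
contribution on a network with `K` links, group payoff is
`b (N c_t - K/m) - N c_t`.

Three analytic conditions decide whether universal contribution is socially
efficient and a Nash equilibrium:

1. **Efficiency**: `b > N c_t / (N c_t - K/m)`;
2. **Deterrence** (minimum in-degree): every individual needs at least
   `ceil( c_t / (c_p (p + b/(N-1))) )` monitors;
3. **Span of control** (maximum out-degree): a contributor can afford at
   most `floor( m (c_t - c_p) )` monitoring links.

Socially optimal networks meet the in-degree bound with equality
(`K = N * min_in`) and concentrate the links on as few monitors as
possible, maximizing the number of *pure contributors* with no enforcement
duties. Cheap punishment (high `p`) drives `min_in` to 1 and the optimal
structures become tree-like; expensive punishment drives `min_in` toward
`N - 1` and only the distributed complete graph remains.

## Worked example

Moderately cheap monitoring and punishment (`m = 6.25`, `p = 2.1`) for a
group of six:

```r
library(coopnet)

pars <- game_params(N = 6, b = 2, m = 6.25, p = 2.1, c_t = 1, c_p = 0.2)
degree_constraints(pars)
#> # A tibble: 1 × 5
#>   min_in max_out K_optimal efficiency_ok feasible
#>    <int>   <int>     <int> <lgl>         <lgl>
#> 1      2       5        12 TRUE          TRUE
```

Each individual needs two monitors, a contributor can afford up to five
monitoring links, and the 12-link optimum passes the efficiency condition.
Sample an optimal network and evaluate the game on it:

```r
spec <- optimal_network_spec(6, d_in = 2, d_out_cap = 5)
net  <- sample_optimal(spec, 1, seed = 7)[[1]]
pure_contributors(net)
#> [1] 1 4 5

pay <- compute_payoffs(net, all_contributors(6), pars)
tidy(pay)
#>    node strategy    monitoring punishment_paid public_good punishment_received payoff
#> 1     1 contributor       0                  0        1                      0  0.232
#> 2     2 contributor       0.32               0        0.68                   0  0.360
#> 3     3 contributor       0.8                0        0.2                    0  0.552
#> 4     4 contributor       0                  0        1                      0  0.232
#> 5     5 contributor       0                  0        1                      0  0.232
#> 6     6 contributor       0.8                0        0.2                    0  0.552

glance(pay)
#> # A tibble: 1 × 5
#>   group_payoff     N     K n_contributors n_free_riders
#> 1         2.16     6    12              6             0

is_nash(net, all_contributors(6), pars)
#> [1] TRUE

krackhardt_scores(net)
#> # A tibble: 1 × 7
#>       N     K connectedness hierarchy efficiency   lub composite
#> 1     6    12             1      0.75       0.72     1      0.54
```

The structure is intermediate: three pure contributors, three monitors, and
a composite hierarchy score of 0.54. Sweeping the (m, p) plane shows the
full distributed-to-hierarchical transition:

```r
sw <- run_sweep(pars, m_grid = c(2.5, 6.25, 20), p_grid = c(0.6, 2.1, 4.6),
                n_samples = 100, seed = 42)
dplyr::filter(sw, feasible) |>
  dplyr::select(m, p, min_in, out_cap, E, H_median, composite_median)
#>       m   p min_in out_cap    E  H_median composite_median
#> 1  2.50 4.6      1       2 0.96 0.9090909        0.8727273
#> 2  6.25 2.1      2       5 0.72 0.7500000        0.5400000
#> 3  6.25 4.6      1       5 0.96 0.8888889        0.8533333
#> 4 20.00 0.6      5       5 0.00 0.0000000        0.0000000
#> 5 20.00 2.1      2       5 0.72 0.7500000        0.5400000
#> 6 20.00 4.6      1       5 0.96 0.8888889        0.8533333

autoplot(sw)   # composite-score heat map over the grid
```

At `p = 0.6` only the complete graph is optimal (composite 0); at `p = 4.6`
optimal networks are near-trees (composite above 0.85). A command-line
wrapper with `conditions` / `generate` / `metrics` / `sweep` subcommands is
installed at `system.file("cli", "coopnet.R", package = "coopnet")`.

See the methods vignette (`vignettes/institutional-networks.Rmd`) for the
full model description, the sampler design, and numerical conventions.

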