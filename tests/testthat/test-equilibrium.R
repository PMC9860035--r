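# Analytic feasibility conditions and the brute-force Nash oracle.

test_that("efficiency condition handles the boundary and degenerate cases", {
  pars <- game_params(N = 6, b = 2, m = 4, p = 1, c_t = 1, c_p = 0.2)
  expect_true(efficiency_condition(pars, K = 0)) # reduces to b > 1

  # equality at the boundary is not enough (strict inequality)
  K <- 6
  b_star <- 6 * 1 / (6 * 1 - K / 4)
  pars_eq <- game_params(N = 6, b = b_star, m = 4, p = 1, c_t = 1, c_p = 0.2)
  expect_false(efficiency_condition(pars_eq, K = K))

  # monitoring costs exceed total contributions: false for any b
  pars_neg <- game_params(N = 6, b = 100, m = 1, p = 1, c_t = 1, c_p = 0.2)
  expect_false(efficiency_condition(pars_neg, K = 30)) # 6 - 30 < 0
})

test_that("minimum in-degree matches the closed form", {
  expect_equal(
    min_in_degree(game_params(N = 6, b = 2, m = 1, p = 1, c_t = 1, c_p = 1)),
    1L # ceil(1 / (1 * 1.4))
  )
  expect_equal(
    min_in_degree(game_params(N = 6, b = 2, m = 1, p = 0.6, c_t = 1, c_p = 0.2)),
    5L # ceil(1 / (0.2 * 1.0))
  )
  # exact-integer argument: ceiling stays at the integer
  expect_equal(
    min_in_degree(game_params(N = 6, b = 2, m = 1, p = 2.1, c_t = 1, c_p = 0.2)),
    2L # 1 / (0.2 * 2.5) = 2 exactly
  )
})

test_that("minimum in-degree equals the smallest deterrent number of monitors", {
  # node 1 is watched by k dedicated monitors; everyone else contributes.
  # Free-riding must be (weakly) unprofitable exactly when k >= min_in.
  for (pars in list(
    game_params(N = 8, b = 2, m = 10, p = 0.8, c_t = 1, c_p = 0.3),
    game_params(N = 8, b = 3, m = 10, p = 0.25, c_t = 1, c_p = 0.5),
    game_params(N = 8, b = 1.5, m = 10, p = 2, c_t = 1, c_p = 0.2)
  )) {
    deterred <- sapply(1:(pars$N - 1), function(k) {
      g <- institution(
        data.frame(source = 1 + seq_len(k), target = rep(1, k)),
        n = pars$N
      )
      base <- compute_payoffs(g, all_contributors(pars$N), pars)
      dev <- coopnet:::deviation_payoff(
        g, all_contributors(pars$N), pars,
        node = 1, x = 0
      )
      dev <= base$allocations$payoff[1] + 1e-9
    })
    oracle_min <- min(which(deterred))
    expect_equal(min_in_degree(pars), oracle_min, info = sprintf("p = %g", pars$p))
    expect_true(all(deterred[oracle_min:length(deterred)]))
  }
})

test_that("maximum out-degree matches the closed form and role affordability", {
  expect_equal(
    max_out_degree(game_params(N = 6, b = 2, m = 4, p = 1, c_t = 1, c_p = 0.25)),
    3L # floor(4 * 0.75)
  )
  expect_equal(
    max_out_degree(game_params(N = 6, b = 2, m = 4, p = 1, c_t = 1, c_p = 1)),
    0L # reserve exhausts the threshold
  )
  # largest k_out for which the contributor role stays affordable
  pars <- game_params(N = 10, b = 2, m = 4.4, p = 1, c_t = 1, c_p = 0.3)
  affordable <- sapply(1:9, function(k) {
    g <- institution(data.frame(source = rep(1, k), target = 1 + seq_len(k)), n = 10)
    !inherits(
      tryCatch(compute_allocations(g, all_contributors(10), pars),
        coopnet_infeasible_role = function(e) e
      ),
      "coopnet_infeasible_role"
    )
  })
  expect_equal(max_out_degree(pars), max(which(affordable)))
  expect_false(any(affordable[(max(which(affordable)) + 1):9]))
})

test_that("degree constraints bundle feasibility correctly", {
  # large m: min_in 5, max_out 40, Eq-1 check at K = 30
  pars <- game_params(N = 6, b = 2, m = 50, p = 0.6, c_t = 1, c_p = 0.2)
  dc <- degree_constraints(pars)
  expect_equal(dc$min_in, 5L)
  expect_equal(dc$max_out, 40L)
  expect_equal(dc$K_optimal, 30L)
  expect_true(dc$feasible) # b = 2 > 6/(6 - 30/50) = 10/9

  # span of control below the required in-degree: infeasible
  pars2 <- game_params(N = 6, b = 2, m = 1, p = 0.6, c_t = 1, c_p = 0.2)
  dc2 <- degree_constraints(pars2)
  expect_true(dc2$max_out < dc2$min_in)
  expect_false(dc2$feasible)

  # cycle-only regime: min_in = max_out = 1
  pars3 <- game_params(N = 6, b = 6, m = 1.5, p = 5, c_t = 1, c_p = 0.3)
  dc3 <- degree_constraints(pars3)
  expect_equal(c(dc3$min_in, dc3$max_out), c(1L, 1L))
  expect_true(dc3$feasible)
  expect_true(is_nash(build_cycle(6), all_contributors(6), pars3))
})

test_that("constraint monotonicity: min_in falls with p and c_p, max_out rises with m", {
  base <- list(N = 8, b = 2, c_t = 1)
  p_grid <- seq(0.2, 6, length.out = 25)
  mi_p <- sapply(p_grid, function(p) {
    min_in_degree(game_params(N = 8, b = 2, m = 1, p = p, c_t = 1, c_p = 0.2))
  })
  expect_true(all(diff(mi_p) <= 0))
  cp_grid <- seq(0.05, 1, length.out = 25)
  mi_cp <- sapply(cp_grid, function(cp) {
    min_in_degree(game_params(N = 8, b = 2, m = 1, p = 1, c_t = 1, c_p = cp))
  })
  expect_true(all(diff(mi_cp) <= 0))
  m_grid <- seq(0.5, 20, length.out = 25)
  mo_m <- sapply(m_grid, function(m) {
    max_out_degree(game_params(N = 8, b = 2, m = m, p = 1, c_t = 1, c_p = 0.2))
  })
  expect_true(all(diff(mo_m) >= 0))
})

test_that("universal free-riding is always a Nash equilibrium", {
  set.seed(11)
  for (rep in 1:10) {
    N <- sample(3:6, 1)
    pars <- random_params(N)
    g <- random_digraph(N, runif(1, 0.2, 0.8))
    expect_true(is_nash(g, all_free_riders(N), pars))
  }
})

test_that("universal contribution is Nash exactly when the analytic constraints hold", {
  set.seed(12)
  agree <- logical(0)
  for (rep in 1:60) {
    N <- sample(3:6, 1)
    pars <- random_params(N)
    g <- random_digraph(N, runif(1, 0.2, 0.9))
    analytic <- constraints_hold(g, pars)
    oracle <- is_nash_or_false(g, all_contributors(N), pars, deviation_grid = 11)
    agree <- c(agree, analytic == oracle)
  }
  expect_true(all(agree))
})

test_that("partial contributions never beat the two pure strategies at equilibrium", {
  # on a feasible optimal network, the fine deviation grid finds nothing
  pars <- game_params(N = 6, b = 2, m = 10, p = 2.1, c_t = 1, c_p = 0.2)
  dc <- degree_constraints(pars)
  expect_true(dc$feasible)
  spec <- optimal_network_spec(6, dc$min_in, min(dc$max_out, 5))
  nets <- sample_optimal(spec, 5, seed = 21)
  for (g in nets) {
    expect_true(is_nash(g, all_contributors(6), pars, deviation_grid = 41))
  }
})

test_that("brute force returns the uniform socially efficient profile", {
  pars <- motif3_params()
  # motif: node 1 is unmonitored, so universal contribution is never Nash
  bf <- brute_force_socially_efficient_nash(motif3(), pars)
  expect_equal(bf$profile, all_free_riders(3))
  expect_equal(bf$group_payoff, 0)

  # cycle with feasible parameters: universal contribution wins
  pars2 <- game_params(N = 4, b = 2, m = 5, p = 4, c_t = 1, c_p = 0.3)
  dc2 <- degree_constraints(pars2)
  expect_true(dc2$feasible)
  expect_equal(dc2$min_in, 1L) # the cycle satisfies the in-degree bound
  bf2 <- brute_force_socially_efficient_nash(build_cycle(4), pars2)
  expect_equal(bf2$profile, all_contributors(4))
  expect_equal(
    bf2$group_payoff,
    pars2$b * (4 - 4 / pars2$m) - 4,
    tolerance = 1e-9
  )

  # infeasible public-goods efficiency: free-riding is socially optimal
  pars3 <- game_params(N = 4, b = 1.05, m = 2, p = 2, c_t = 1, c_p = 0.3)
  expect_false(efficiency_condition(pars3, K = 4))
  bf3 <- brute_force_socially_efficient_nash(build_cycle(4), pars3)
  expect_equal(bf3$profile, all_free_riders(4))

  expect_error(
    brute_force_socially_efficient_nash(build_cycle(13), game_params(
      N = 13, b = 2, m = 5, p = 2, c_t = 1, c_p = 0.3
    )),
    "N <= 12"
  )
})
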