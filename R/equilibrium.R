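# Analytic equilibrium/feasibility conditions and a brute-force Nash checker.
#
# Universal threshold contribution is socially efficient and a Nash
# equilibrium when three conditions hold:
#   (i)   b > N c_t / (N c_t - K/m)        -- benefits cover monitoring costs;
#   (ii)  every node's in-degree is at least
#             ceil( c_t / ( c_p (p + b/(N-1)) ) )
#         -- enough punishers watching each individual;
#   (iii) every node's out-degree is at most floor( m (c_t - c_p) )
#         -- each monitor can afford its role under the threshold.
# Networks exist only when max out-degree >= min in-degree, and the socially
# optimal ones minimise links: K = N * (minimum in-degree).

#' Public-goods efficiency condition
#'
#' Tests whether universal threshold contribution is more socially efficient
#' than universal free-riding on a network with `K` links: the group payoff
#' under universal contribution, `b (N c_t - K/m) - N c_t`, is positive
#' exactly when `b > N c_t / (N c_t - K/m)`. When monitoring costs exceed
#' the total contribution (`N c_t - K/m <= 0`) no efficiency is possible and
#' the condition is `FALSE` for any `b`.
#'
#' @param params A [game_params] object.
#' @param K Total number of directed links in the network.
#' @return `TRUE` or `FALSE` (strict inequality; equality returns `FALSE`).
#' @examples
#' pars <- game_params(N = 6, b = 2, m = 4, p = 1, c_t = 1, c_p = 0.2)
#' efficiency_condition(pars, K = 6)
#' @export
efficiency_condition <- function(params, K) {
  stopifnot(inherits(params, "game_params"), K >= 0)
  denom <- params$N * params$c_t - K / params$m
  if (denom <= 0) {
    return(FALSE)
  }
  params$b > params$N * params$c_t / denom
}

#' Degree constraints set by the punishment and monitoring efficiencies
#'
#' `min_in_degree()` returns the minimum number of monitors each individual
#' needs for free-riding to be unprofitable,
#' `ceil( c_t / ( c_p (p + b/(N-1)) ) )`: free-riding saves `c_t` but costs
#' `p c_p` in punishment per punisher plus the forgone public-good share
#' `b c_p / (N-1)` that each punisher's reserve would otherwise generate.
#'
#' `max_out_degree()` returns each individual's span of control,
#' `floor( m (c_t - c_p) )`: monitoring `k` individuals costs `k/m` and must
#' leave room for the punishment reserve under the threshold.
#'
#' `degree_constraints()` bundles the two and reports feasibility: networks
#' where universal contribution is socially efficient and Nash exist iff
#' `max_out >= min_in` and [efficiency_condition()] holds at the minimal link
#' count `K = N * min_in`.
#'
#' @param params A [game_params] object.
#' @return `min_in_degree()`, `max_out_degree()`: an integer.
#'   `degree_constraints()`: a one-row tibble with `min_in`, `max_out`,
#'   `K_optimal`, `efficiency_ok`, and `feasible`.
#' @examples
#' pars <- game_params(N = 6, b = 2, m = 4, p = 1, c_t = 1, c_p = 0.2)
#' degree_constraints(pars)
#' @export
min_in_degree <- function(params) {
  stopifnot(inherits(params, "game_params"))
  val <- params$c_t / (params$c_p * (params$p + params$b / (params$N - 1)))
  # ceiling on the exact value; the incentive condition is weak at the boundary
  as.integer(ceiling(val - .coopnet_tol))
}

#' @rdname min_in_degree
#' @export
max_out_degree <- function(params) {
  stopifnot(inherits(params, "game_params"))
  as.integer(floor(params$m * (params$c_t - params$c_p) + .coopnet_tol))
}

#' @rdname min_in_degree
#' @export
degree_constraints <- function(params) {
  min_in <- min_in_degree(params)
  max_out <- max_out_degree(params)
  K_opt <- params$N * min_in
  eff <- efficiency_condition(params, K_opt)
  tibble::tibble(
    min_in = min_in,
    max_out = max_out,
    K_optimal = as.integer(K_opt),
    efficiency_ok = eff,
    feasible = max_out >= min_in && eff
  )
}

# Payoff to `node` when it unilaterally deviates to a total spend of x
# (everything else per `profile`). Returns NA when the deviation itself is
# infeasible (x = c_t with an unaffordable role).
deviation_payoff <- function(network, profile, params, node, x) {
  ev <- eval_profile(network, profile, params, deviator = node, x = x)
  if (is.null(ev)) {
    return(NA_real_)
  }
  ev$payoffs[node]
}

#' Nash equilibrium check by exhaustive unilateral deviations
#'
#' A profile is a Nash equilibrium when no individual can strictly increase
#' their own payoff by unilaterally changing their strategy. Besides the two
#' pure strategies (contribute exactly `c_t`, or nothing), partial
#' contributions are checked on a uniform grid of total spends in
#' `[0, c_t]`; a partial payer allocates monitoring first, then the
#' punishment reserve, then the public good, and is treated as a punishable
#' free-rider by its monitors. The grid is a numerical safety net for the
#' analytic result that only the two pure strategies survive at equilibrium.
#'
#' @inheritParams compute_allocation
#' @param deviation_grid Number of equally spaced spends in `[0, c_t]` to
#'   test per node (including both endpoints). `deviation_grid = 2` checks
#'   only the pure label switch.
#' @param tol Payoff tolerance: a deviation must improve the incumbent
#'   payoff by more than `tol` to refute the equilibrium.
#' @return `TRUE` or `FALSE`.
#' @examples
#' pars <- game_params(N = 6, b = 2, m = 10, p = 5, c_t = 1, c_p = 0.2)
#' is_nash(build_cycle(6), all_contributors(6), pars)
#' @export
is_nash <- function(network, profile, params, deviation_grid = 21,
                    tol = 1e-9) {
  network <- as_institution(network)
  stopifnot(deviation_grid >= 2)
  n <- igraph::vcount(network)
  check_profile(profile, n)
  base <- eval_profile(network, profile, params) # errors if role unaffordable
  xs <- seq(0, params$c_t, length.out = deviation_grid)
  for (i in seq_len(n)) {
    incumbent <- base$payoffs[i]
    for (x in xs) {
      dev <- deviation_payoff(network, profile, params, i, x)
      if (!is.na(dev) && dev > incumbent + tol) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Socially efficient Nash profile by brute force
#'
#' Enumerates all `2^N` assignments of the two pure strategies, keeps those
#' that are Nash equilibria under pure label-switch deviations, and returns
#' the one with the highest group payoff. Ties are broken toward universal
#' contribution, then lexicographically (contributors first). Profiles in
#' which some contributor cannot afford its institutional role are excluded.
#'
#' Intended as an independent oracle on small groups; guarded at `N <= 12`.
#'
#' @inheritParams compute_allocation
#' @return A list with `profile` (the strategy vector) and `group_payoff`.
#' @examples
#' pars <- game_params(N = 3, b = 2, m = 4, p = 3, c_t = 1, c_p = 0.25)
#' g <- institution(data.frame(source = c(1, 2, 3), target = c(2, 3, 1)), n = 3)
#' brute_force_socially_efficient_nash(g, pars)$profile
#' @export
brute_force_socially_efficient_nash <- function(network, params) {
  network <- as_institution(network)
  n <- igraph::vcount(network)
  stopifnot(n == params$N)
  if (n > 12) {
    stop("Brute-force enumeration is limited to N <= 12 (2^N profiles).",
      call. = FALSE
    )
  }
  best <- NULL
  best_pi <- -Inf
  best_rank <- NULL
  for (code in 0:(2^n - 1)) {
    fr <- which(bitwAnd(code, bitwShiftL(1L, 0:(n - 1))) != 0)
    profile <- strategy_profile(n, free_riders = fr)
    ev <- tryCatch(
      eval_profile(network, profile, params),
      coopnet_infeasible_role = function(e) NULL
    )
    if (is.null(ev)) next
    # Nash under label switches: flip each node's label
    nash <- TRUE
    for (i in seq_len(n)) {
      x_dev <- if (profile[i] == "contributor") 0 else params$c_t
      dev <- deviation_payoff(network, profile, params, i, x_dev)
      if (!is.na(dev) && dev > ev$payoffs[i] + .coopnet_tol) {
        nash <- FALSE
        break
      }
    }
    if (!nash) next
    # rank for tie-breaking: fewer free-riders first, then lexicographic
    rank <- c(length(fr), code)
    if (ev$group_payoff > best_pi + .coopnet_tol ||
      (abs(ev$group_payoff - best_pi) <= .coopnet_tol &&
        (is.null(best_rank) ||
          rank[1] < best_rank[1] ||
          (rank[1] == best_rank[1] && rank[2] < best_rank[2])))) {
      best <- profile
      best_pi <- ev$group_payoff
      best_rank <- rank
    }
  }
  list(profile = best, group_payoff = best_pi)
}
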