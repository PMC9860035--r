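# Core payoff engine for the public goods game on an institutional network.
#
# Allocation rules (applied per node, in order):
#   * a pure free-rider spends nothing and contributes nothing;
#   * a contributor with no monitoring duties (k_out = 0) contributes the
#     full threshold c_t to the public good;
#   * a contributor with k_out > 0 first pays k_out / m for monitoring, then
#     holds the reserve c_p: if any monitored individual free-rides, the
#     reserve is split equally over those free-riders as punishment,
#     otherwise it goes to the public good; the remainder (always
#     c_t - k_out/m, minus c_p when punishment occurs) is the public-good
#     contribution.
#
# Payoffs:  pi_i = b/(N-1) * sum_{j != i} g_j  -  (own total spend)
#                  -  p * (punishment allocated against i),
# where g_j is j's public-good contribution.

.coopnet_tol <- 1e-9

#' Strategy profiles
#'
#' A strategy profile is a character vector of length `N` with entries
#' `"contributor"` (threshold contributor, pays exactly `c_t` following the
#' institutional role) or `"free_rider"` (contributes nothing, absorbs any
#' punishment). These are the only two strategies that can occur in a Nash
#' equilibrium of the game.
#'
#' @param n Group size.
#' @param free_riders Integer node ids that free-ride (the rest contribute).
#' @return A character vector of length `n`.
#' @examples
#' strategy_profile(3, free_riders = 2)
#' @export
strategy_profile <- function(n, free_riders = integer(0)) {
  stopifnot(n >= 1, all(free_riders %in% seq_len(n)))
  s <- rep("contributor", n)
  s[free_riders] <- "free_rider"
  s
}

#' @rdname strategy_profile
#' @export
all_contributors <- function(n) strategy_profile(n)

#' @rdname strategy_profile
#' @export
all_free_riders <- function(n) strategy_profile(n, free_riders = seq_len(n))

check_profile <- function(profile, n) {
  if (length(profile) != n) {
    stop("Strategy profile length (", length(profile),
      ") does not match network size (", n, ").",
      call. = FALSE
    )
  }
  bad <- setdiff(unique(profile), c("contributor", "free_rider"))
  if (length(bad) > 0) {
    stop("Unknown strategy labels: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(profile)
}

infeasible_role_error <- function(node, k_out, params) {
  stop(rlang::error_cnd(
    class = "coopnet_infeasible_role",
    message = sprintf(
      paste0(
        "Node %d cannot afford its institutional role: monitoring %d ",
        "individuals costs %g and the punishment reserve is %g, together ",
        "exceeding the contribution threshold c_t = %g."
      ),
      node, k_out, k_out / params$m, params$c_p, params$c_t
    )
  ))
}

# Evaluate allocations/payoffs for a profile, optionally with one node
# deviating to an arbitrary total spend x in [0, c_t]. Returns NULL when the
# deviating node's target allocation is infeasible (role unaffordable at
# x = c_t); an infeasible role for a non-deviating contributor is an error.
eval_profile <- function(network, profile, params, deviator = NULL, x = NULL) {
  n <- igraph::vcount(network)
  check_profile(profile, n)
  stopifnot(n == params$N)

  k_out <- igraph::degree(network, mode = "out")
  out_nbrs <- igraph::adjacent_vertices(network, seq_len(n), mode = "out")

  spend <- ifelse(profile == "contributor", params$c_t, 0)
  full <- profile == "contributor"
  if (!is.null(deviator)) {
    spend[deviator] <- x
    full[deviator] <- x >= params$c_t - .coopnet_tol
  }
  free <- !full

  g <- numeric(n) # public-good contributions
  mon <- numeric(n) # monitoring spend
  pun_paid <- numeric(n) # total punishment spend
  pr <- numeric(n) # punishment allocated against each node
  pun_targets <- vector("list", n)

  for (i in seq_len(n)) {
    xi <- spend[i]
    if (xi <= .coopnet_tol && !full[i]) next # pure free-rider: all zero
    ki <- k_out[i]
    if (full[i]) {
      if (ki == 0) {
        g[i] <- params$c_t
        next
      }
      remainder <- params$c_t - ki / params$m - params$c_p
      if (remainder < -.coopnet_tol) {
        if (!is.null(deviator) && i == deviator) {
          return(NULL) # deviating to an unaffordable role: unavailable
        }
        infeasible_role_error(i, ki, params)
      }
      mon[i] <- ki / params$m
      targets <- as.integer(out_nbrs[[i]])
      fr <- targets[free[targets]]
      if (length(fr) > 0) {
        pun_paid[i] <- params$c_p
        share <- params$c_p / length(fr)
        pr[fr] <- pr[fr] + share
        pun_targets[[i]] <- stats::setNames(rep(share, length(fr)), fr)
        g[i] <- remainder
      } else {
        g[i] <- params$c_t - ki / params$m # reserve goes to the public good
      }
    } else {
      # partial payer: monitoring first, then reserve, then public good
      mon[i] <- min(xi, ki / params$m)
      rem <- xi - mon[i]
      targets <- as.integer(out_nbrs[[i]])
      fr <- targets[free[targets]]
      if (ki > 0 && length(fr) > 0 && rem > .coopnet_tol) {
        pun_paid[i] <- min(rem, params$c_p)
        share <- pun_paid[i] / length(fr)
        pr[fr] <- pr[fr] + share
        pun_targets[[i]] <- stats::setNames(rep(share, length(fr)), fr)
        rem <- rem - pun_paid[i]
      }
      g[i] <- rem
    }
  }

  benefit <- params$b / (n - 1) * (sum(g) - g)
  payoffs <- benefit - spend - params$p * pr

  list(
    g = g, mon = mon, pun_paid = pun_paid, pun_targets = pun_targets,
    punishment_received = pr, spend = spend, payoffs = payoffs,
    group_payoff = sum(payoffs)
  )
}

#' Allocation of one individual's contribution
#'
#' Splits an individual's threshold contribution between monitoring,
#' punishment, and the public good given their institutional role and the
#' strategies of the individuals they monitor. A contributor's first priority
#' is monitoring (each monitored individual costs `1/m`); individuals with
#' monitoring duties hold the reserve `c_p`, splitting it equally over any
#' free-riders they monitor (or contributing it to the public good if there
#' are none); whatever remains under `c_t` goes to the public good.
#' Free-riders spend nothing.
#'
#' @param i Node id.
#' @param network A directed igraph institutional network.
#' @param profile A strategy profile (see [strategy_profile()]).
#' @param params A [game_params] object with `params$N` equal to the network
#'   size.
#' @return A list with `monitoring_spend`, `punishment_spend` (named numeric,
#'   one entry per punished node), `public_good_contribution`, and
#'   `punishment_received` (amount allocated against `i` by its monitors,
#'   before multiplication by `p`).
#' @examples
#' g <- institution(data.frame(source = c(1, 1), target = c(2, 3)), n = 3)
#' pars <- game_params(N = 3, b = 2, m = 4, p = 3, c_t = 1, c_p = 0.25)
#' compute_allocation(1, g, all_contributors(3), pars)
#' @export
compute_allocation <- function(i, network, profile, params) {
  network <- as_institution(network)
  stopifnot(i %in% seq_len(igraph::vcount(network)))
  ev <- eval_profile(network, profile, params)
  pt <- ev$pun_targets[[i]]
  list(
    monitoring_spend = ev$mon[i],
    punishment_spend = if (is.null(pt)) stats::setNames(numeric(0), character(0)) else pt,
    public_good_contribution = ev$g[i],
    punishment_received = ev$punishment_received[i]
  )
}

#' Allocations and payoffs for a whole group
#'
#' `compute_allocations()` returns the per-node allocation table;
#' `compute_payoffs()` additionally computes each individual's payoff
#' \deqn{\pi_i = \frac{b}{N-1} \sum_{j \ne i} g_j - s_i - p \, r_i,}
#' where \eqn{g_j} is \eqn{j}'s public-good contribution, \eqn{s_i} is
#' \eqn{i}'s own total spend (\eqn{c_t} for a contributor, 0 for a
#' free-rider), and \eqn{r_i} is the punishment allocated against \eqn{i}.
#'
#' @inheritParams compute_allocation
#' @return `compute_allocations()`: a tibble with one row per node (`node`,
#'   `strategy`, `k_out`, `monitoring`, `punishment_paid`, `public_good`,
#'   `punishment_received`). `compute_payoffs()`: a `coopnet_payoffs` object
#'   with elements `allocations` (that tibble plus a `payoff` column),
#'   `group_payoff` (\eqn{\Pi_N = \sum_i \pi_i}), and the call ingredients;
#'   use [generics::tidy()] / [generics::glance()] to extract tidy tables.
#' @examples
#' g <- institution(data.frame(source = c(1, 1), target = c(2, 3)), n = 3)
#' pars <- game_params(N = 3, b = 2, m = 4, p = 3, c_t = 1, c_p = 0.25)
#' compute_payoffs(g, all_contributors(3), pars)
#' @export
compute_allocations <- function(network, profile, params) {
  network <- as_institution(network)
  ev <- eval_profile(network, profile, params)
  tibble::tibble(
    node = seq_along(ev$g),
    strategy = profile,
    k_out = as.integer(igraph::degree(network, mode = "out")),
    monitoring = ev$mon,
    punishment_paid = ev$pun_paid,
    public_good = ev$g,
    punishment_received = ev$punishment_received
  )
}

#' @rdname compute_allocations
#' @export
compute_payoffs <- function(network, profile, params) {
  network <- as_institution(network)
  ev <- eval_profile(network, profile, params)
  alloc <- tibble::tibble(
    node = seq_along(ev$g),
    strategy = profile,
    monitoring = ev$mon,
    punishment_paid = ev$pun_paid,
    public_good = ev$g,
    punishment_received = ev$punishment_received,
    payoff = ev$payoffs
  )
  structure(
    list(
      allocations = alloc,
      group_payoff = ev$group_payoff,
      params = params,
      N = params$N,
      K = igraph::ecount(network)
    ),
    class = "coopnet_payoffs"
  )
}

#' @export
print.coopnet_payoffs <- function(x, ...) {
  cat(sprintf(
    "<coopnet_payoffs> N = %d, K = %d links, group payoff = %g\n",
    x$N, x$K, x$group_payoff
  ))
  print(x$allocations)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a payoff result
#'
#' @param x A `coopnet_payoffs` object from [compute_payoffs()].
#' @param ... Unused.
#' @return `tidy()`: the per-node allocation/payoff tibble. `glance()`: a
#'   one-row tibble with `group_payoff`, `N`, `K`, and the strategy counts.
#' @method tidy coopnet_payoffs
#' @export
tidy.coopnet_payoffs <- function(x, ...) x$allocations

#' @rdname tidy.coopnet_payoffs
#' @method glance coopnet_payoffs
#' @export
glance.coopnet_payoffs <- function(x, ...) {
  tibble::tibble(
    group_payoff = x$group_payoff,
    N = x$N,
    K = x$K,
    n_contributors = sum(x$allocations$strategy == "contributor"),
    n_free_riders = sum(x$allocations$strategy == "free_rider")
  )
}
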