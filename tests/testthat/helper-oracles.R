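# Independent oracles used to cross-check the implementation. These work from
# the adjacency matrix with plain depth-first search, deliberately avoiding
# the igraph routines the package itself relies on.

# Reachability by DFS: R[i, j] TRUE when a directed path runs i -> ... -> j
# (diagonal TRUE: every node reaches itself).
oracle_reachability <- function(adj) {
  n <- nrow(adj)
  r <- diag(n) > 0
  for (start in seq_len(n)) {
    stack <- which(adj[start, ] > 0)
    seen <- rep(FALSE, n)
    while (length(stack) > 0) {
      v <- stack[[1]]
      stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      stack <- c(stack, which(adj[v, ] > 0 & !seen))
    }
    r[start, seen] <- TRUE
  }
  r
}

# Graph hierarchy recomputed from the DFS closure.
oracle_hierarchy <- function(adj) {
  r <- oracle_reachability(adj)
  diag(r) <- FALSE
  linked <- r | t(r)
  recip <- r & t(r)
  nl <- sum(linked[upper.tri(linked)])
  if (nl == 0) {
    return(NA_real_)
  }
  1 - sum(recip[upper.tri(recip)]) / nl
}

adjacency_of <- function(network) {
  as.matrix(igraph::as_adjacency_matrix(network, sparse = FALSE))
}

# Simple random directed graph (no loops, no parallel links).
random_digraph <- function(n, prob) {
  adj <- matrix(stats::runif(n * n) < prob, n, n)
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  institution(data.frame(source = idx[, 1], target = idx[, 2]), n = n)
}

# The three-person motif: node 1 monitors nodes 2 and 3.
motif3 <- function() {
  institution(data.frame(source = c(1, 1), target = c(2, 3)), n = 3)
}

motif3_params <- function() {
  game_params(N = 3, b = 2, m = 4, p = 3, c_t = 1, c_p = 0.25)
}

# Random parameter set with c_t = 1.
random_params <- function(N) {
  game_params(
    N = N,
    b = stats::runif(1, 1.1, 4),
    m = stats::runif(1, 0.5, 10),
    p = stats::runif(1, 0.2, 6),
    c_t = 1,
    c_p = stats::runif(1, 0.05, 1)
  )
}

# Does universal contribution satisfy the analytic constraints on g?
constraints_hold <- function(network, params) {
  k_in <- igraph::degree(network, mode = "in")
  k_out <- igraph::degree(network, mode = "out")
  affordable <- all(k_out == 0 | k_out / params$m + params$c_p <= params$c_t + 1e-9)
  all(k_in >= min_in_degree(params)) && affordable
}

is_nash_or_false <- function(network, profile, params, ...) {
  tryCatch(
    is_nash(network, profile, params, ...),
    coopnet_infeasible_role = function(e) FALSE
  )
}
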