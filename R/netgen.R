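# Canonical socially-optimal network constructions and a random sampler for
# degree-constrained optimal networks (in-degree exactly d_in at every node,
# out-degrees <= d_out_cap, K = N * d_in links, pure contributors maximized).

#' Canonical institutional network topologies
#'
#' `build_complete()` returns the fully distributed network: every individual
#' monitors every other (all `N(N-1)` ordered links). `build_out_tree()`
#' returns the maximally hierarchical topology: a rooted tree with all links
#' pointing away from the root, filled breadth-first left-to-right with at
#' most `span` children per node (`K = N - 1`; the root is unmonitored, so
#' this pure out-tree is used for metric calibration, not as a game
#' solution). `build_rooted_tree_with_reciprocal()` adds one link from the
#' root's first child back to the root so that every node, including the
#' root, has in-degree exactly 1 (`K = N`) — the socially optimal tree-like
#' structure when one monitor per individual suffices.
#' `build_cycle()` returns the directed ring `1 -> 2 -> ... -> N -> 1`
#' (`K = N`, all degrees 1) — the only optimal network when both the minimum
#' in-degree and the span of control equal 1.
#'
#' @param N Number of nodes (`N >= 2`).
#' @param span Maximum number of children per node (`span >= 1`).
#' @return A directed igraph network.
#' @examples
#' build_out_tree(6, span = 2)
#' build_rooted_tree_with_reciprocal(6, span = 5)
#' @export
build_complete <- function(N) {
  stopifnot(N >= 2)
  as_institution(igraph::make_full_graph(N, directed = TRUE))
}

#' @rdname build_complete
#' @export
build_out_tree <- function(N, span) {
  stopifnot(N >= 2, span >= 1)
  children <- 2:N
  parents <- (children - 2L) %/% span + 1L
  institution(data.frame(source = parents, target = children), n = N)
}

#' @rdname build_complete
#' @export
build_rooted_tree_with_reciprocal <- function(N, span) {
  tree <- build_out_tree(N, span)
  as_institution(igraph::add_edges(tree, c(2, 1)))
}

#' @rdname build_complete
#' @export
build_cycle <- function(N) {
  stopifnot(N >= 2)
  institution(
    data.frame(source = seq_len(N), target = c(2:N, 1L)),
    n = N
  )
}

#' Specification of a socially optimal network family
#'
#' The socially optimal networks for a feasible parameter set are those with
#' in-degree exactly `d_in` (the minimum in-degree, see [min_in_degree()]) at
#' every node, out-degrees at most `d_out_cap` (the span of control, see
#' [max_out_degree()]), hence exactly `K = N * d_in` links, and — among
#' those — the maximum number of pure contributors (out-degree-0 nodes). The
#' out-degree cap is clamped to `N - 1` since no individual can monitor more
#' than everyone else. Concentrating all `N * d_in` out-links on as few
#' monitors as possible gives `n_monitors = ceiling(N * d_in / cap)` and
#' `n_pure_contributors = N - n_monitors`.
#'
#' @param N Number of nodes.
#' @param d_in Required in-degree for every node (`>= 1`).
#' @param d_out_cap Maximum out-degree per node; must be at least `d_in` for
#'   any network to exist.
#' @return An `optimal_network_spec` object (a named list with `N`, `d_in`,
#'   `d_out_cap` as supplied, the effective `cap`, `n_monitors`, and
#'   `n_pure_contributors`).
#' @examples
#' optimal_network_spec(12, d_in = 1, d_out_cap = 3)
#' @export
optimal_network_spec <- function(N, d_in, d_out_cap) {
  stopifnot(
    N >= 2, d_in >= 1, d_in == as.integer(d_in),
    d_out_cap == as.integer(d_out_cap)
  )
  if (d_in > N - 1) {
    stop("d_in cannot exceed N - 1 (no self-monitoring).", call. = FALSE)
  }
  if (d_out_cap < d_in) {
    stop(
      "Infeasible: the out-degree cap (", d_out_cap,
      ") is below the required in-degree (", d_in, ").",
      call. = FALSE
    )
  }
  cap <- min(d_out_cap, N - 1L)
  n_monitors <- as.integer(ceiling(N * d_in / cap))
  structure(
    list(
      N = as.integer(N), d_in = as.integer(d_in),
      d_out_cap = as.integer(d_out_cap), cap = as.integer(cap),
      n_monitors = n_monitors,
      n_pure_contributors = as.integer(N - n_monitors)
    ),
    class = "optimal_network_spec"
  )
}

#' @export
print.optimal_network_spec <- function(x, ...) {
  cat(sprintf(
    "<optimal_network_spec> N = %d, d_in = %d, out cap = %d, K = %d, %d monitors / %d pure contributors\n",
    x$N, x$d_in, x$cap, x$N * x$d_in, x$n_monitors, x$n_pure_contributors
  ))
  invisible(x)
}

# Number of compositions of s into k parts, each in [1, cap]; dense DP.
count_compositions <- function(s, k, cap) {
  if (k == 0) {
    return(as.numeric(s == 0))
  }
  # counts[j] = number of ways to write j with the parts processed so far
  counts <- numeric(s + 1)
  counts[1] <- 1 # zero parts, sum 0
  for (part in seq_len(k)) {
    nxt <- numeric(s + 1)
    for (j in 0:s) {
      if (counts[j + 1] == 0) next
      top <- min(cap, s - j)
      if (top >= 1) {
        idx <- (j + 1):(j + top)
        nxt[idx + 1] <- nxt[idx + 1] + counts[j + 1]
      }
    }
    counts <- nxt
  }
  counts[s + 1]
}

# Draw a uniform composition of s into k parts each in [1, cap].
sample_composition <- function(s, k, cap) {
  parts <- integer(k)
  for (i in seq_len(k)) {
    rem_parts <- k - i
    lo <- max(1L, s - rem_parts * cap)
    hi <- min(cap, s - rem_parts)
    vals <- lo:hi
    w <- vapply(vals, function(v) count_compositions(s - v, rem_parts, cap), numeric(1))
    parts[i] <- if (length(vals) == 1) vals else vals[sample.int(length(vals), 1, prob = w)]
    s <- s - parts[i]
  }
  parts
}

#' Randomly sample socially optimal networks
#'
#' Draws networks satisfying an [optimal_network_spec()]: `n_monitors`
#' randomly chosen monitor nodes share the `N * d_in` out-links (their
#' out-degrees are a uniform random composition with each part in
#' `[1, cap]`), every node receives exactly `d_in` in-links, and the result
#' is simple (no self-loops or parallel links) and weakly connected. Each
#' monitor's targets are drawn sequentially without replacement with
#' probability proportional to the targets' remaining in-capacity (stub
#' matching conditioned on simplicity); draws that dead-end, produce
#' duplicates, or come out disconnected are discarded and retried, up to
#' `retry_cap` attempts per sample.
#'
#' @param spec An [optimal_network_spec()].
#' @param n_samples Number of networks to draw.
#' @param seed Optional integer seed; given the same seed the function
#'   returns identical samples (the caller's RNG state is untouched).
#' @param retry_cap Maximum attempts per sample before giving up (an error
#'   signalling a combinatorially tight specification).
#' @return A list of `n_samples` igraph networks.
#' @examples
#' nets <- sample_optimal(optimal_network_spec(12, 1, 3), 5, seed = 1)
#' sapply(nets, igraph::ecount) # all K = 12
#' @export
sample_optimal <- function(spec, n_samples, seed = NULL, retry_cap = 10000) {
  stopifnot(inherits(spec, "optimal_network_spec"), n_samples >= 1)
  draw_all <- function() {
    lapply(seq_len(n_samples), function(s) draw_one(spec, retry_cap))
  }
  if (is.null(seed)) draw_all() else withr::with_seed(seed, draw_all())
}

draw_one <- function(spec, retry_cap) {
  N <- spec$N
  S <- N * spec$d_in
  for (attempt in seq_len(retry_cap)) {
    monitors <- sample.int(N, spec$n_monitors)
    s_out <- sample_composition(S, spec$n_monitors, spec$cap)
    in_cap <- rep(spec$d_in, N)
    edges <- matrix(0L, nrow = S, ncol = 2)
    row <- 1L
    ok <- TRUE
    for (idx in seq_along(monitors)) {
      mo <- monitors[idx]
      cand <- which(in_cap > 0)
      cand <- cand[cand != mo]
      if (length(cand) < s_out[idx]) {
        ok <- FALSE
        break
      }
      targets <- if (length(cand) == 1) {
        cand
      } else {
        cand[sample.int(length(cand), s_out[idx], prob = in_cap[cand])]
      }
      in_cap[targets] <- in_cap[targets] - 1L
      rows <- row:(row + s_out[idx] - 1L)
      edges[rows, 1] <- mo
      edges[rows, 2] <- targets
      row <- row + s_out[idx]
    }
    if (!ok) next
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    if (igraph::vcount(g) < N) g <- igraph::add_vertices(g, N - igraph::vcount(g))
    if (!igraph::is_connected(g, mode = "weak")) next
    return(g)
  }
  stop(
    "sample_optimal: gave up after ", retry_cap,
    " attempts; the specification is combinatorially too tight.",
    call. = FALSE
  )
}
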