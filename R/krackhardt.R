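# Krackhardt's four dimensions of hierarchy for directed graphs, plus the
# composite E x H score used to compare institutional networks. All pair
# counts are over unordered node pairs and the linkage relation is
# reachability: nodes a and b are "linked" when a path runs from a to b or
# from b to a, and "reciprocally linked" when paths run both ways.

#' Reachability relation of a directed network
#'
#' @param network A directed igraph network.
#' @return An `N x N` logical matrix `R` with `R[i, j]` `TRUE` when a
#'   directed path (of length >= 1, or i == j) runs from `i` to `j`.
#' @export
reachability <- function(network) {
  network <- as_institution(network)
  igraph::distances(network, mode = "out") < Inf
}

pair_linkage <- function(network) {
  r <- reachability(network)
  diag(r) <- FALSE
  linked <- r | t(r)
  reciprocal <- r & t(r)
  list(
    linked = sum(linked[upper.tri(linked)]),
    reciprocal = sum(reciprocal[upper.tri(reciprocal)])
  )
}

#' Graph hierarchy (H)
#'
#' One minus the fraction of reciprocally linked unordered node pairs among
#' linked pairs, computed on the reachability relation. An out-tree has no
#' reciprocally linked pairs, so `H = 1`; in a complete digraph every pair is
#' reciprocally linked, so `H = 0`.
#'
#' @param network A directed igraph network.
#' @return A number in `[0, 1]`.
#' @examples
#' graph_hierarchy(build_out_tree(6, 2)) # 1
#' graph_hierarchy(build_complete(6)) # 0
#' @export
graph_hierarchy <- function(network) {
  pl <- pair_linkage(network)
  if (pl$linked == 0) {
    stop("Graph hierarchy is undefined on a network with no linked pairs.",
      call. = FALSE
    )
  }
  1 - pl$reciprocal / pl$linked
}

#' Graph efficiency (E)
#'
#' One minus the proportion of surplus links beyond the `N - 1` needed to
#' connect a single component:
#' `E = 1 - (K - (N-1)) / (N(N-1) - (N-1))`.
#' An out-tree (`K = N - 1`) scores 1; the complete digraph (`K = N(N-1)`,
#' the maximum possible) scores 0. Defined here for single-component
#' (weakly connected) networks only.
#'
#' @inheritParams graph_hierarchy
#' @return A number in `[0, 1]`.
#' @export
graph_efficiency <- function(network) {
  network <- as_institution(network)
  if (!igraph::is_connected(network, mode = "weak")) {
    stop("Graph efficiency is only defined for single-component networks.",
      call. = FALSE
    )
  }
  n <- igraph::vcount(network)
  k <- igraph::ecount(network)
  1 - (k - (n - 1)) / (n * (n - 1) - (n - 1))
}

#' Connectedness
#'
#' One minus the fraction of unordered node pairs that fall in different
#' weak components; 1 exactly when the network is weakly connected.
#'
#' @inheritParams graph_hierarchy
#' @return A number in `[0, 1]`.
#' @export
connectedness <- function(network) {
  network <- as_institution(network)
  n <- igraph::vcount(network)
  stopifnot(n >= 2)
  sizes <- igraph::components(network, mode = "weak")$csize
  cross_pairs <- (n^2 - sum(sizes^2)) / 2
  1 - cross_pairs / (n * (n - 1) / 2)
}

#' Least upper boundedness (LUB)
#'
#' One minus the fraction of unordered node pairs lacking a common ancestor
#' (a node, possibly one of the two, with directed paths to both), relative
#' to the worst case of `(N-1)(N-2)/2` violating pairs. In a rooted
#' out-tree the root bounds every pair, so LUB is 1; in a complete digraph
#' every node reaches both members of every pair. Defined here for weakly
#' connected networks only.
#'
#' @inheritParams graph_hierarchy
#' @return A number in `[0, 1]`.
#' @export
least_upper_boundedness <- function(network) {
  network <- as_institution(network)
  if (!igraph::is_connected(network, mode = "weak")) {
    stop("Least upper boundedness is only defined for single-component networks.",
      call. = FALSE
    )
  }
  n <- igraph::vcount(network)
  r <- reachability(network) # includes the diagonal: a node bounds itself
  # pair (i, j) has an upper bound iff some k reaches both
  has_bound <- crossprod(r) > 0 # t(r) %*% r: common ancestor counts
  violations <- sum(!has_bound[upper.tri(has_bound)])
  worst <- (n - 1) * (n - 2) / 2
  if (worst == 0) {
    return(as.numeric(violations == 0))
  }
  1 - violations / worst
}

#' All Krackhardt scores of a network
#'
#' Computes the four dimensions (connectedness, graph hierarchy `H`, graph
#' efficiency `E`, least upper boundedness) and the composite hierarchy
#' score `E * H`. The composite runs from 0 for the fully distributed
#' complete digraph to 1 for an out-tree.
#'
#' @inheritParams graph_hierarchy
#' @return A one-row tibble with columns `N`, `K`, `connectedness`,
#'   `hierarchy`, `efficiency`, `lub`, and `composite`.
#' @examples
#' krackhardt_scores(build_rooted_tree_with_reciprocal(6, 5))
#' @export
krackhardt_scores <- function(network) {
  network <- as_institution(network)
  h <- graph_hierarchy(network)
  e <- graph_efficiency(network)
  tibble::tibble(
    N = igraph::vcount(network),
    K = igraph::ecount(network),
    connectedness = connectedness(network),
    hierarchy = h,
    efficiency = e,
    lub = least_upper_boundedness(network),
    composite = e * h
  )
}
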