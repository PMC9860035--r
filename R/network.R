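#' Institutional monitoring/punishment networks
#'
#' An institutional network is a simple directed graph on `N` individuals:
#' a link `i -> j` means individual `i` is responsible for monitoring
#' individual `j` and punishing `j` if `j` free-rides. Self-loops and
#' parallel links are forbidden; reciprocal pairs (`i -> j` and `j -> i`)
#' are allowed. Networks are represented as [igraph::igraph] objects.
#'
#' `institution()` builds a network from an edge table; `as_institution()`
#' validates an existing igraph object.
#'
#' @param edges A data frame (or two-column matrix) of directed links with
#'   columns `source` and `target` holding node ids in `1..n`.
#' @param n Number of nodes. Isolated nodes (no links) are permitted, so `n`
#'   must be supplied rather than inferred.
#' @return A directed [igraph::igraph] with `n` vertices.
#' @examples
#' # the 3-person motif: X (node 1) monitors Y (2) and Z (3)
#' g <- institution(data.frame(source = c(1, 1), target = c(2, 3)), n = 3)
#' igraph::degree(g, mode = "in")
#' @export
institution <- function(edges, n) {
  stopifnot(length(n) == 1, n >= 1, n == as.integer(n))
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    if (!all(c("source", "target") %in% names(edges))) {
      names(edges)[1:2] <- c("source", "target")
    }
    el <- cbind(edges$source, edges$target)
    storage.mode(el) <- "double"
  } else {
    el <- matrix(numeric(0), ncol = 2)
  }
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  } else if (igraph::vcount(g) > n) {
    stop("Edge list references node ids above n = ", n, call. = FALSE)
  }
  as_institution(g)
}

#' @rdname institution
#' @param g A directed igraph object.
#' @export
as_institution <- function(g) {
  stopifnot(inherits(g, "igraph"))
  if (!igraph::is_directed(g)) {
    stop("An institutional network must be a directed graph.", call. = FALSE)
  }
  if (igraph::any_loop(g)) {
    stop("Self-loops are not allowed: an individual never monitors itself.",
      call. = FALSE
    )
  }
  if (igraph::any_multiple(g)) {
    stop("Parallel links are not allowed: links are binary.", call. = FALSE)
  }
  g
}

#' Degree summaries of an institutional network
#'
#' @param network A directed igraph network (see [institution()]).
#' @return A tibble with one row per node: `node`, `k_in` (number of
#'   monitors watching the node), `k_out` (number of individuals the node
#'   monitors).
#' @export
network_degrees <- function(network) {
  network <- as_institution(network)
  tibble::tibble(
    node = seq_len(igraph::vcount(network)),
    k_in = as.integer(igraph::degree(network, mode = "in")),
    k_out = as.integer(igraph::degree(network, mode = "out"))
  )
}

#' Pure contributors of a network
#'
#' Pure contributors are individuals with no monitoring or punishment
#' responsibilities, i.e. nodes with out-degree zero. They contribute the
#' entire threshold directly to the public good.
#'
#' @inheritParams network_degrees
#' @return An integer vector of node ids.
#' @examples
#' pure_contributors(build_out_tree(6, span = 5)) # the five leaves
#' @export
pure_contributors <- function(network) {
  network <- as_institution(network)
  which(igraph::degree(network, mode = "out") == 0)
}

#' Read and write institutional networks
#'
#' Two plain-text formats are supported, inferred from the file extension:
#' `.csv` edge lists with header `source,target` and 0-based node ids, and
#' `.graphml`. Because edge lists cannot express trailing isolated nodes,
#' `read_network()` accepts `n` to pad the vertex count.
#'
#' @param path File path ending in `.csv` or `.graphml`.
#' @param n Optional node count for edge-list input (defaults to the largest
#'   node id seen).
#' @return `read_network()` returns an igraph network; `write_network()`
#'   returns `path` invisibly.
#' @export
read_network <- function(path, n = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(as_institution(g))
  }
  if (ext == "csv") {
    edges <- utils::read.csv(path)
    stopifnot(all(c("source", "target") %in% names(edges)))
    n_seen <- if (nrow(edges) > 0) max(edges$source, edges$target) + 1L else 0L
    n <- if (is.null(n)) n_seen else max(n, n_seen)
    return(institution(
      data.frame(source = edges$source + 1L, target = edges$target + 1L),
      n = n
    ))
  }
  stop("Unsupported network file extension: ", ext, call. = FALSE)
}

#' @rdname read_network
#' @param network A directed igraph network.
#' @export
write_network <- function(network, path) {
  network <- as_institution(network)
  ext <- tolower(tools::file_ext(path))
  if (ext == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else if (ext == "csv") {
    el <- igraph::as_edgelist(network, names = FALSE)
    utils::write.csv(
      data.frame(source = el[, 1] - 1L, target = el[, 2] - 1L),
      path,
      row.names = FALSE, quote = FALSE
    )
  } else {
    stop("Unsupported network file extension: ", ext, call. = FALSE)
  }
  invisible(path)
}
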