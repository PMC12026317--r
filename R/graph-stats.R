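# Structural statistics feeding the gravity models: degree, triangles,
# local clustering, k-shell decomposition, hop distances, diameter,
# truncation radius and effective-influence sets.

#' Per-node structural statistics and network aggregates
#'
#' Computes, for every node: degree \eqn{k_i}, triangle-edge count
#' \eqn{n_i} (edges among its neighbours), local clustering coefficient
#' \eqn{C_i = 2 n_i / (k_i (k_i - 1))} (defined as 0 when \eqn{k_i \le 1}),
#' and k-shell index \eqn{ks_i} from iterative degree pruning (isolated
#' nodes get shell 0). Network aggregates: `kmax`, `ksmax`, hop diameter of
#' the largest connected component, truncation radius `R`, mean degree and
#' mean shortest path length.
#'
#' @param g undirected simple graph.
#' @return An object of class `node_statistics`: a list with a per-node
#'   data frame `nodes` (columns `node`, `degree`, `triangle_edges`,
#'   `clustering`, `kshell`) and scalar aggregates `n_nodes`, `n_edges`,
#'   `kmax`, `ksmax`, `diameter`, `radius`, `mean_degree`,
#'   `mean_path_length`.
#' @examples
#' stats <- node_statistics(figure1_network())
#' stats$nodes
#' @export
node_statistics <- function(g) {
  .check_graph(g)
  g <- .canonical_graph(g)
  ids <- igraph::V(g)$name
  k <- as.integer(igraph::degree(g))
  n_tri <- as.integer(igraph::count_triangles(g))
  cc <- ifelse(k >= 2, 2 * n_tri / (k * (k - 1)), 0)
  ks <- as.integer(igraph::coreness(g))
  n <- igraph::gorder(g)
  diam <- if (n >= 2) graph_diameter(g) else NA_integer_
  res <- list(
    nodes = data.frame(
      node = ids, degree = k, triangle_edges = n_tri,
      clustering = cc, kshell = ks,
      stringsAsFactors = FALSE, row.names = NULL
    ),
    n_nodes = n,
    n_edges = igraph::gsize(g),
    kmax = if (n) max(k) else 0L,
    ksmax = if (n) max(ks) else 0L,
    diameter = diam,
    radius = if (is.na(diam)) NA_integer_ else truncation_radius(g, diameter = diam),
    mean_degree = if (n) mean(k) else NA_real_,
    mean_path_length = if (n >= 2) igraph::mean_distance(g, directed = FALSE) else NA_real_
  )
  class(res) <- "node_statistics"
  res
}

#' @export
print.node_statistics <- function(x, ...) {
  cat(sprintf("Node statistics: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  kmax = %d, ksmax = %d, diameter = %s, R = %s\n",
              x$kmax, x$ksmax, x$diameter, x$radius))
  cat(sprintf("  mean degree = %.4f, mean path length = %.4f\n",
              x$mean_degree, x$mean_path_length))
  print(utils::head(x$nodes, 10), ...)
  if (nrow(x$nodes) > 10) cat("  ...\n")
  invisible(x)
}

#' Hop distances from a single source node
#'
#' Breadth-first shortest path lengths in hops; unreachable nodes are
#' `Inf`; the source itself is 0.
#'
#' @param g graph.
#' @param source node id.
#' @return Named numeric vector over all nodes in canonical order.
#' @export
hop_distances_from <- function(g, source) {
  .check_graph(g)
  g <- .canonical_graph(g)
  source <- .check_node(g, source)
  d <- igraph::distances(g, v = source, mode = "all")[1, ]
  d[igraph::V(g)$name]
}

#' Hop diameter
#'
#' Maximum finite pairwise hop distance, computed on the largest connected
#' component of the graph.
#'
#' @param g graph with at least two nodes.
#' @return Integer hop count.
#' @export
graph_diameter <- function(g) {
  .check_graph(g)
  if (igraph::gorder(g) <= 1) {
    stop("diameter is undefined for graphs with fewer than 2 nodes", call. = FALSE)
  }
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  as.integer(igraph::diameter(sub, directed = FALSE, unconnected = FALSE))
}

#' Truncation radius
#'
#' The hop-distance cutoff beyond which a node's influence is neglected:
#' half the network diameter, floored, never below 1.
#'
#' @param g graph.
#' @param diameter optionally a precomputed diameter (hops).
#' @return Integer radius `max(1, floor(diameter / 2))`.
#' @export
truncation_radius <- function(g, diameter = NULL) {
  if (is.null(diameter)) diameter <- graph_diameter(g)
  max(1L, as.integer(floor(diameter / 2)))
}

#' Effective-influence node sets
#'
#' For each node i, the set \eqn{\varphi_i} of nodes within hop distance R
#' of i (excluding i itself). These are the only targets for which i's
#' attractions are evaluated in the truncated gravity model. Sets never
#' cross connected components.
#'
#' @param g graph.
#' @param radius hop cutoff R; defaults to [truncation_radius()].
#' @return An object of class `influence_sets`: list with `sets` (named
#'   list of character vectors, canonical node order) and `radius`.
#' @examples
#' influence_sets(figure1_network())$sets[["2"]]  # "1" "5"
#' @export
influence_sets <- function(g, radius = NULL) {
  .check_graph(g)
  g <- .canonical_graph(g)
  if (is.null(radius)) radius <- truncation_radius(g)
  stopifnot(radius >= 1)
  ids <- igraph::V(g)$name
  d <- igraph::distances(g, mode = "all")
  sets <- lapply(seq_along(ids), function(i) {
    ids[is.finite(d[i, ]) & d[i, ] >= 1 & d[i, ] <= radius]
  })
  names(sets) <- ids
  structure(list(sets = sets, radius = as.integer(radius)), class = "influence_sets")
}

#' @export
print.influence_sets <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("Effective-influence sets (R = %d): %d nodes, total pairs = %d\n",
              x$radius, length(x$sets), sum(sizes)))
  invisible(x)
}
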