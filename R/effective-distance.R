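# Effective distance: an asymmetric, probability-derived notion of distance.
# A one-hop move from i to an adjacent j happens with probability
# P_{j|i} = 1/k_i, giving the directed edge length
# D_{j|i} = 1 - log2(P_{j|i}) = 1 + log2(k_i).
# Multi-hop distances are shortest additive paths over these directed
# lengths; every length is >= 1, so Dijkstra applies.

# directed weighted graph carrying the one-hop effective lengths
.effective_graph <- function(g) {
  k <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0L) {
    gd <- igraph::make_empty_graph(igraph::gorder(g), directed = TRUE)
    igraph::V(gd)$name <- igraph::V(g)$name
    return(gd)
  }
  both <- rbind(el, el[, 2:1, drop = FALSE])
  gd <- igraph::graph_from_edgelist(both, directed = TRUE)
  # keep isolated vertices and names aligned with g
  gd <- igraph::add_vertices(gd, igraph::gorder(g) - igraph::gorder(gd))
  igraph::V(gd)$name <- igraph::V(g)$name
  igraph::E(gd)$weight <- 1 + log2(k[both[, 1]])
  gd
}

#' Direct (one-hop) effective length
#'
#' For adjacent nodes i, j the effective distance from i to j is
#' \eqn{1 - \log_2(1/k_i) = 1 + \log_2(k_i)}: a high-degree source spreads
#' its unit of attention thin, so each of its neighbours is effectively
#' farther away. Asymmetric whenever the two degrees differ.
#'
#' @param g graph.
#' @param from,to adjacent node ids.
#' @return The effective length, a number \eqn{\ge 1}.
#' @examples
#' g <- figure1_network()
#' direct_effective_length(g, "2", "1")  # 2: node 2 has degree 2
#' direct_effective_length(g, "1", "2")  # 1 + log2(6)
#' @export
direct_effective_length <- function(g, from, to) {
  .check_graph(g)
  from <- .check_node(g, from)
  to <- .check_node(g, to)
  if (!igraph::are_adjacent(g, from, to)) {
    stop("nodes ", from, " and ", to, " are not adjacent; ",
         "use effective_distances_from() for multi-hop pairs", call. = FALSE)
  }
  unname(1 + log2(igraph::degree(g, from)))
}

#' Single-source effective distances
#'
#' Shortest additive effective-path distances from `source` to the given
#' targets (Dijkstra over the directed one-hop lengths). Unreachable
#' targets are `Inf`.
#'
#' @param g graph.
#' @param source node id.
#' @param targets character vector of target ids, or `"all"` (default).
#' @return Named numeric vector of distances \eqn{D_{j|source}}.
#' @export
effective_distances_from <- function(g, source, targets = "all") {
  .check_graph(g)
  g <- .canonical_graph(g)
  source <- .check_node(g, source)
  gd <- .effective_graph(g)
  all_ids <- igraph::V(g)$name
  to <- if (identical(targets, "all")) all_ids else vapply(targets, .check_node, "", g = g)
  if (length(to) == 0L) return(stats::setNames(numeric(0), character(0)))
  d <- igraph::distances(gd, v = source, to = to, mode = "out",
                         weights = igraph::E(gd)$weight)[1, ]
  stats::setNames(as.numeric(d), to)
}

#' All-pairs effective distances
#'
#' @param g graph.
#' @return A dense matrix `D` with `D[i, j]` the effective distance from i
#'   to j (rows are sources), node ids as dimnames, diagonal 0, `Inf`
#'   across components.
#' @export
effective_distance_matrix <- function(g) {
  .check_graph(g)
  g <- .canonical_graph(g)
  gd <- .effective_graph(g)
  d <- igraph::distances(gd, mode = "out", weights = igraph::E(gd)$weight)
  ids <- igraph::V(g)$name
  dimnames(d) <- list(ids, ids)
  d
}

#' Effective distances restricted to the influence sets
#'
#' Computes and stores \eqn{D_{j|i}} for exactly the pairs with
#' \eqn{j \in \varphi_i} — nothing else — which is where the truncated
#' model's computational saving comes from.
#'
#' @param g graph.
#' @param phi an [influence_sets()] object built on `g`.
#' @return An object of class `effective_distance_map`: a data frame with
#'   columns `source`, `target`, `distance`, sorted by (source, target) in
#'   canonical order, with attributes `restricted = TRUE`, `radius`, and
#'   `n_pairs`.
#' @export
effective_distances_restricted <- function(g, phi = influence_sets(g)) {
  .check_graph(g)
  g <- .canonical_graph(g)
  if (!inherits(phi, "influence_sets")) {
    stop("phi must be an influence_sets object", call. = FALSE)
  }
  ids <- igraph::V(g)$name
  if (!setequal(names(phi$sets), ids)) {
    stop("influence sets do not match the graph's node set", call. = FALSE)
  }
  gd <- .effective_graph(g)
  w <- igraph::E(gd)$weight
  rows <- lapply(ids, function(i) {
    tg <- phi$sets[[i]]
    if (length(tg) == 0L) return(NULL)
    d <- igraph::distances(gd, v = i, to = tg, mode = "out", weights = w)[1, ]
    data.frame(source = i, target = tg, distance = as.numeric(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(source = character(0), target = character(0),
                      distance = numeric(0))
  }
  structure(out, restricted = TRUE, radius = phi$radius,
            n_pairs = nrow(out),
            class = c("effective_distance_map", "data.frame"))
}

#' Export an effective-distance map as a text table
#'
#' Three columns (source, target, distance), tab-separated, sorted by
#' (source, target).
#'
#' @param map an `effective_distance_map` (or any source/target/distance
#'   data frame).
#' @param path output path.
#' @export
write_effective_distances <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(map)
}
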