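# Node-importance measures: the four traditional centralities (degree,
# betweenness, closeness, k-shell), the gravity family (GM, EDGM, GGM),
# and the local effective distance-integrated gravity model (LEDGM) with
# its unrestricted all-pairs variant (R-LEDGM).
#
# Every function returns a `centrality_scores` object: the method tag, a
# named numeric score vector in canonical node order, and a parameter
# record (alpha, radius, ...) so any table is regenerable from its output.

.new_scores <- function(method, scores, params = list()) {
  structure(list(method = method, scores = scores, params = params),
            class = "centrality_scores")
}

#' @export
print.centrality_scores <- function(x, ...) {
  cat(sprintf("Centrality scores (%s), %d nodes", x$method, length(x$scores)))
  if (length(x$params)) {
    cat(" [", paste(names(x$params), unlist(x$params), sep = " = ",
                    collapse = ", "), "]", sep = "")
  }
  cat("\n")
  print(round(x$scores, 6), ...)
  invisible(x)
}

#' @export
as.data.frame.centrality_scores <- function(x, ...) {
  data.frame(node = names(x$scores), score = unname(x$scores),
             method = x$method, stringsAsFactors = FALSE)
}

#' Degree centrality
#'
#' Score of node i is its degree \eqn{k_i}: the number of direct
#' neighbours.
#'
#' @param g undirected simple graph.
#' @return A `centrality_scores` object.
#' @export
degree_centrality <- function(g) {
  .check_graph(g)
  g <- .canonical_graph(g)
  k <- igraph::degree(g)
  .new_scores("dc", stats::setNames(as.numeric(k), igraph::V(g)$name))
}

#' Betweenness centrality
#'
#' For each node i, the sum over unordered pairs \{j, k\} (both distinct
#' from i) of the fraction of shortest j–k paths that pass through i.
#' Unnormalized.
#'
#' @inheritParams degree_centrality
#' @return A `centrality_scores` object.
#' @export
betweenness_centrality <- function(g) {
  .check_graph(g)
  g <- .canonical_graph(g)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  .new_scores("bc", stats::setNames(as.numeric(b), igraph::V(g)$name))
}

#' Closeness centrality
#'
#' \eqn{(N - 1) / \sum_j d_{ij}} with hop distances. On a disconnected
#' graph each node is scored within its own component using that
#' component's size (with a warning); an isolated node scores 0.
#'
#' @inheritParams degree_centrality
#' @return A `centrality_scores` object.
#' @export
closeness_centrality <- function(g) {
  .check_graph(g)
  g <- .canonical_graph(g)
  ids <- igraph::V(g)$name
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warning("graph is disconnected; closeness computed within components",
            call. = FALSE)
  }
  d <- igraph::distances(g, mode = "all")
  cc <- vapply(seq_along(ids), function(i) {
    members <- comp$membership == comp$membership[i]
    nc <- sum(members)
    if (nc <= 1) return(0)
    (nc - 1) / sum(d[i, members])
  }, numeric(1))
  .new_scores("cc", stats::setNames(cc, ids))
}

#' K-shell centrality
#'
#' Score of node i is its k-shell (coreness) index from iterative degree
#' pruning: repeatedly remove all nodes of degree at most k, assign them
#' shell k, and increment k.
#'
#' @inheritParams degree_centrality
#' @return A `centrality_scores` object.
#' @export
kshell_centrality <- function(g) {
  .check_graph(g)
  g <- .canonical_graph(g)
  ks <- igraph::coreness(g)
  .new_scores("ks", stats::setNames(as.numeric(ks), igraph::V(g)$name))
}

# shared gravity sum over hop distances: mass[i] * mass[j] / d_ij^2
# over pairs with 1 <= d_ij <= radius
.hop_gravity <- function(g, mass, radius) {
  d <- igraph::distances(g, mode = "all")
  ok <- is.finite(d) & d >= 1 & d <= radius
  contrib <- matrix(0, nrow(d), ncol(d))
  contrib[ok] <- 1 / d[ok]^2
  as.numeric(mass * (contrib %*% mass))
}

#' Gravity-model centrality (GM)
#'
#' \eqn{GM_i = \sum_{d_{ij} \le R, j \ne i} k_i k_j / d_{ij}^2}: degree as
#' mass, hop distance as distance, truncated at radius R.
#'
#' @param g undirected simple graph.
#' @param radius truncation radius; defaults to [truncation_radius()].
#' @return A `centrality_scores` object with the radius in its parameter
#'   record.
#' @export
gravity_gm <- function(g, radius = NULL) {
  .check_graph(g)
  g <- .canonical_graph(g)
  if (is.null(radius)) radius <- truncation_radius(g)
  k <- as.numeric(igraph::degree(g))
  s <- .hop_gravity(g, k, radius)
  .new_scores("gm", stats::setNames(s, igraph::V(g)$name),
              list(radius = radius))
}

#' Effective-distance gravity model (EDGM)
#'
#' \eqn{EDGM_i = \sum_{j \ne i} k_i k_j / D_{j|i}^2} over all other nodes,
#' with \eqn{D_{j|i}} the shortest effective-path distance. Pairs in
#' different components (infinite distance) contribute 0.
#'
#' @inheritParams degree_centrality
#' @return A `centrality_scores` object.
#' @export
gravity_edgm <- function(g) {
  .check_graph(g)
  g <- .canonical_graph(g)
  k <- as.numeric(igraph::degree(g))
  d <- effective_distance_matrix(g)
  ok <- is.finite(d) & d > 0
  inv2 <- matrix(0, nrow(d), ncol(d))
  inv2[ok] <- 1 / d[ok]^2
  s <- k * as.numeric(inv2 %*% k)
  .new_scores("edgm", stats::setNames(s, igraph::V(g)$name))
}

#' Generalized gravity model (GGM)
#'
#' Gravity sum over hop distances \eqn{d_{ij} \le R} with mass
#' \eqn{Sp_i = e^{-\alpha C_i} k_i}, discounting the degree of nodes whose
#' neighbourhoods are tightly clustered. With `alpha = 0` the GGM reduces
#' exactly to the plain gravity model.
#'
#' @inheritParams gravity_gm
#' @param alpha clustering-penalty exponent, \eqn{\alpha \ge 0}; default 1.
#' @return A `centrality_scores` object with `alpha` and the radius in its
#'   parameter record.
#' @export
gravity_ggm <- function(g, radius = NULL, alpha = 1) {
  .check_graph(g)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0)
  g <- .canonical_graph(g)
  if (is.null(radius)) radius <- truncation_radius(g)
  stats <- node_statistics(g)
  mass <- exp(-alpha * stats$nodes$clustering) * stats$nodes$degree
  s <- .hop_gravity(g, mass, radius)
  .new_scores("ggm", stats::setNames(s, igraph::V(g)$name),
              list(radius = radius, alpha = alpha))
}

#' Propagation capability
#'
#' The node mass used by the LEDGM:
#' \eqn{sp_i = e^{-C_i} (k_i / k_{max} + ks_i / ks_{max})}, fusing local
#' clustering, degree and core position into one spreading-power measure.
#'
#' @param stats a [node_statistics()] object, or a graph (statistics are
#'   computed on the fly).
#' @return Named numeric vector of \eqn{sp_i} in canonical node order.
#' @examples
#' sp <- propagation_capability(figure1_network())
#' round(sp[c("2", "1")], 4)  # 0.4905, 1.4331
#' @export
propagation_capability <- function(stats) {
  if (igraph::is_igraph(stats)) stats <- node_statistics(stats)
  if (!inherits(stats, "node_statistics")) {
    stop("expected a node_statistics object or a graph", call. = FALSE)
  }
  if (stats$ksmax == 0 || stats$kmax == 0) {
    stop("propagation capability is undefined on an edgeless graph ",
         "(kmax and ksmax must be positive)", call. = FALSE)
  }
  with(stats$nodes, stats::setNames(
    exp(-clustering) * (degree / stats$kmax + kshell / stats$ksmax), node))
}

#' Pairwise attraction
#'
#' The gravitational pull between two nodes:
#' \eqn{W_{i,j} = sp_i \, sp_j / D_{j|i}^2}. An infinite distance yields 0.
#'
#' @param sp_i,sp_j propagation capabilities of the two nodes.
#' @param distance effective distance \eqn{D_{j|i}} from i to j (> 0).
#' @return The attraction, a non-negative number.
#' @export
pairwise_attraction <- function(sp_i, sp_j, distance) {
  stopifnot(distance > 0)
  if (!is.finite(distance)) return(0)
  unname(sp_i * sp_j / distance^2)
}

# shared LEDGM kernel: sum sp_i * sp_j / D_{j|i}^2 over the given targets
.ledgm_scores <- function(g, sp, target_sets, dist_lookup) {
  ids <- names(sp)
  vapply(ids, function(i) {
    tg <- target_sets[[i]]
    if (length(tg) == 0L) return(0)
    d <- dist_lookup(i, tg)
    ok <- is.finite(d) & d > 0
    sum(sp[[i]] * sp[tg[ok]] / d[ok]^2)
  }, numeric(1))
}

#' LEDGM: local effective distance-integrated gravity model
#'
#' The full pipeline: truncation radius R from half the hop diameter,
#' effective-influence sets \eqn{\varphi_i} (nodes within hop distance R),
#' effective distances restricted to those sets, propagation capabilities
#' \eqn{sp_i}, and finally
#' \eqn{IEDG_i = \sum_{j \in \varphi_i} sp_i \, sp_j / D_{j|i}^2}.
#'
#' @param g undirected simple graph with at least one edge.
#' @param radius optional override of the truncation radius.
#' @return A `centrality_scores` object with the radius in its parameter
#'   record.
#' @examples
#' round(ledgm(figure1_network())$scores, 4)
#' @export
ledgm <- function(g, radius = NULL) {
  .check_graph(g)
  g <- .canonical_graph(g)
  if (igraph::gsize(g) == 0) {
    stop("LEDGM is undefined on an edgeless graph", call. = FALSE)
  }
  if (is.null(radius)) radius <- truncation_radius(g)
  phi <- influence_sets(g, radius)
  sp <- propagation_capability(node_statistics(g))
  gd <- .effective_graph(g)
  w <- igraph::E(gd)$weight
  lookup <- function(i, tg) {
    igraph::distances(gd, v = i, to = tg, mode = "out", weights = w)[1, ]
  }
  s <- .ledgm_scores(g, sp, phi$sets, lookup)
  .new_scores("ledgm", s, list(radius = phi$radius))
}

#' R-LEDGM: the unrestricted all-pairs variant
#'
#' As [ledgm()] but summing over every other node with all-pairs effective
#' distances — no effective-influence truncation. Used to quantify what
#' the truncation buys: scores where \eqn{\varphi_i} already spans the
#' whole component are identical.
#'
#' @inheritParams degree_centrality
#' @return A `centrality_scores` object.
#' @export
ledgm_unrestricted <- function(g) {
  .check_graph(g)
  g <- .canonical_graph(g)
  if (igraph::gsize(g) == 0) {
    stop("LEDGM is undefined on an edgeless graph", call. = FALSE)
  }
  ids <- igraph::V(g)$name
  sp <- propagation_capability(node_statistics(g))
  d <- effective_distance_matrix(g)
  sets <- lapply(ids, function(i) setdiff(ids, i))
  names(sets) <- ids
  s <- .ledgm_scores(g, sp, sets, function(i, tg) d[i, tg])
  .new_scores("rledgm", s)
}

#' Rank nodes by centrality score
#'
#' Descending score; ties broken by ascending node id (numeric-aware).
#'
#' @param scores a `centrality_scores` object.
#' @param k number of top nodes to keep; defaults to all. If `k` exceeds
#'   the node count it is truncated with a warning.
#' @return A data frame with columns `rank`, `node`, `score`.
#' @export
rank_nodes <- function(scores, k = NULL) {
  stopifnot(inherits(scores, "centrality_scores"))
  s <- scores$scores
  n <- length(s)
  if (is.null(k)) k <- n
  if (k > n) {
    warning("k = ", k, " exceeds the number of nodes (", n, "); truncated",
            call. = FALSE)
    k <- n
  }
  ord <- order(-s, .id_order_rank(names(s)))
  top <- ord[seq_len(k)]
  data.frame(rank = seq_len(k), node = names(s)[top], score = unname(s[top]),
             stringsAsFactors = FALSE)
}

# rank vector giving each id's position in canonical id order
.id_order_rank <- function(ids) {
  r <- integer(length(ids))
  r[.id_order(ids)] <- seq_along(ids)
  r
}

# registry used by the evaluation harness and the CLI
.centrality_methods <- function() {
  list(
    dc = function(g, ...) degree_centrality(g),
    bc = function(g, ...) betweenness_centrality(g),
    cc = function(g, ...) closeness_centrality(g),
    ks = function(g, ...) kshell_centrality(g),
    gm = function(g, radius = NULL, ...) gravity_gm(g, radius),
    edgm = function(g, ...) gravity_edgm(g),
    ggm = function(g, radius = NULL, alpha = 1, ...) gravity_ggm(g, radius, alpha),
    ledgm = function(g, radius = NULL, ...) ledgm(g, radius),
    rledgm = function(g, ...) ledgm_unrestricted(g)
  )
}

#' Compute a centrality by method name
#'
#' Dispatcher over the eight implemented measures, as used by the
#' evaluation harness and the command-line interface.
#'
#' @param g graph.
#' @param method one of `"dc"`, `"bc"`, `"cc"`, `"ks"`, `"gm"`, `"edgm"`,
#'   `"ggm"`, `"ledgm"`, `"rledgm"`.
#' @param radius optional truncation-radius override (gm, ggm, ledgm).
#' @param alpha clustering exponent for ggm.
#' @return A `centrality_scores` object.
#' @export
node_centrality <- function(g, method, radius = NULL, alpha = 1) {
  reg <- .centrality_methods()
  method <- match.arg(method, names(reg))
  reg[[method]](g, radius = radius, alpha = alpha)
}
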