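# Ranking-quality evaluation: Kendall tau-a against the SI-derived
# standard influence ranking, top-k overlap between methods, and the
# timing/operation-count comparison of the truncated vs all-pairs model.

#' Kendall rank correlation (tau-a)
#'
#' \eqn{\tau = 2 (n_a - n_b) / (N (N - 1))} where \eqn{n_a} and \eqn{n_b}
#' count concordant and discordant pairs of the paired sequences. Tied
#' pairs count as neither, with no tie correction to the denominator
#' (tau-a), so heavy ties shrink \eqn{|\tau|}'s attainable range.
#'
#' @param x,y paired numeric score vectors of equal length \eqn{N \ge 2}.
#' @return \eqn{\tau \in [-1, 1]}.
#' @examples
#' kendall_tau_a(c(1, 2, 3, 4), c(1, 3, 2, 4))  # (5 - 1) * 2 / 12
#' @export
kendall_tau_a <- function(x, y) {
  if (length(x) != length(y)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  n <- length(x)
  stopifnot(n >= 2)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  s <- sx * sy
  up <- upper.tri(s)
  na <- sum(s[up] > 0)
  nb <- sum(s[up] < 0)
  2 * (na - nb) / (n * (n - 1))
}

#' Top-k overlap between two rankings
#'
#' Size of the intersection of the two top-k node sets.
#'
#' @param a,b rankings as returned by [rank_nodes()] (data frames with a
#'   `node` column), or plain vectors of node ids in rank order.
#' @param k depth of the comparison; must not exceed either length.
#' @return Integer in \[0, k\].
#' @export
top_k_overlap <- function(a, b, k) {
  ids_a <- if (is.data.frame(a)) a$node else as.character(a)
  ids_b <- if (is.data.frame(b)) b$node else as.character(b)
  stopifnot(k >= 1, k <= length(ids_a), k <= length(ids_b))
  length(intersect(ids_a[seq_len(k)], ids_b[seq_len(k)]))
}

#' Kendall tau-a of centrality methods across an infection-rate grid
#'
#' For each infection rate beta: build the SI standard influence vector
#' (every node seeded alone, `runs` repetitions, mean infected count at
#' the horizon), then correlate each method's scores with it under
#' [kendall_tau_a()]. This is the accuracy comparison behind the
#' rate-sweep evaluation.
#'
#' @param g undirected simple graph.
#' @param methods character vector of method tags (see
#'   [node_centrality()]).
#' @param betas numeric vector of infection probabilities.
#' @param steps,runs SI horizon and repetition count.
#' @param seed master RNG seed; each beta gets its own derived sub-seed.
#' @param alpha,radius forwarded to the centrality methods.
#' @return A data frame with columns `beta`, `method`, `tau`, plus the SI
#'   parameters as attributes.
#' @export
kendall_vs_beta_sweep <- function(g, methods = c("dc", "bc", "cc", "gm",
                                                 "edgm", "ggm", "ledgm"),
                                  betas = c(0.1, 0.2, 0.3), steps = 10,
                                  runs = 100, seed = NULL, alpha = 1,
                                  radius = NULL) {
  .check_graph(g)
  g <- .canonical_graph(g)
  scores <- lapply(methods, function(m) {
    node_centrality(g, m, radius = radius, alpha = alpha)$scores
  })
  names(scores) <- methods
  ids <- igraph::V(g)$name
  rows <- lapply(seq_along(betas), function(b) {
    sub_seed <- if (is.null(seed)) NULL else .derive_seed(seed, b)
    infl <- single_seed_influence(g, beta = betas[b], steps = steps,
                                  runs = runs, seed = sub_seed)
    data.frame(
      beta = betas[b],
      method = methods,
      tau = vapply(methods, function(m) {
        kendall_tau_a(scores[[m]][ids], infl[ids])
      }, numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "steps") <- steps
  attr(out, "runs") <- runs
  attr(out, "seed") <- seed
  out
}

#' Truncated vs all-pairs timing and operation counts
#'
#' Runs [ledgm()] and [ledgm_unrestricted()] on the same graph and reports
#' wall-clock times together with the deterministic surrogate that does
#' not depend on hardware: the number of source-target effective-distance
#' pairs each variant evaluates (\eqn{\sum_i |\varphi_i|} vs
#' \eqn{N (N - 1)}).
#'
#' Wall-clock numbers are environment-dependent and are reported for
#' orientation only; the pair counts are the comparable quantity.
#'
#' @param g undirected simple graph.
#' @return A list with `times` (named elapsed seconds), `pairs_restricted`,
#'   `pairs_unrestricted`, `reduction` (fraction of pairs avoided),
#'   `radius`, and the two score objects.
#' @export
timing_benchmark <- function(g) {
  .check_graph(g)
  g <- .canonical_graph(g)
  n <- igraph::gorder(g)
  phi <- influence_sets(g)
  t_r <- system.time(s_r <- ledgm(g))[["elapsed"]]
  t_u <- system.time(s_u <- ledgm_unrestricted(g))[["elapsed"]]
  pairs_r <- sum(lengths(phi$sets))
  pairs_u <- n * (n - 1)
  list(
    times = c(ledgm = t_r, rledgm = t_u),
    pairs_restricted = pairs_r,
    pairs_unrestricted = pairs_u,
    reduction = 1 - pairs_r / pairs_u,
    radius = phi$radius,
    scores = list(ledgm = s_r, rledgm = s_u)
  )
}
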