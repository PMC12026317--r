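# Discrete-time Susceptible-Infected simulation: the ground-truth
# benchmark for spreading power. Synchronous updates: at each step every
# infected node independently attempts to infect each susceptible
# neighbour with probability beta; newly infected nodes transmit from the
# next step on; nobody recovers.
#
# A susceptible node with m infected neighbours therefore becomes
# infected with probability 1 - (1 - beta)^m, which is simulated with one
# uniform draw per susceptible node per step (equivalent in distribution
# to the per-contact Bernoulli trials, and vectorizable).

# deterministic per-run sub-seed from a master seed; extending the run
# count never perturbs earlier runs
.derive_seed <- function(seed, index) {
  as.integer(((as.double(seed) %% 2147483647) * 48271 + 7919 * index) %% 2147483647)
}

.si_step_matrix <- function(g) {
  # sparse adjacency in canonical order for fast infected-neighbour counts
  igraph::as_adjacency_matrix(g, sparse = TRUE)
}

.si_run <- function(A, beta, steps, seed_idx) {
  n <- nrow(A)
  infected <- logical(n)
  infected[seed_idx] <- TRUE
  counts <- integer(steps + 1L)
  counts[1L] <- sum(infected)
  for (t in seq_len(steps)) {
    if (!all(infected)) {
      m <- as.numeric(A %*% infected)
      p <- 1 - (1 - beta)^m
      new_inf <- !infected & stats::runif(n) < p
      infected <- infected | new_inf
    }
    counts[t + 1L] <- sum(infected)
  }
  counts
}

.check_si_params <- function(g, beta, steps, seeds, runs) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1,
            steps >= 0, runs >= 1)
  if (length(seeds) == 0L) {
    stop("SI simulation requires at least one seed node", call. = FALSE)
  }
  vapply(as.character(seeds), .check_node, "", g = g)
}

#' One SI trajectory
#'
#' A single realization of the susceptible-infected process.
#'
#' @param g undirected simple graph.
#' @param beta per-contact infection probability in \[0, 1\].
#' @param steps number of time steps.
#' @param seeds node ids initially infected.
#' @param seed optional RNG seed for this run.
#' @return Integer vector of length `steps + 1`: the infected count at
#'   t = 0 ... steps. Monotone non-decreasing, starts at `length(seeds)`,
#'   bounded by the node count.
#' @export
simulate_si_once <- function(g, beta, steps, seeds, seed = NULL) {
  .check_graph(g)
  g <- .canonical_graph(g)
  seeds <- .check_si_params(g, beta, steps, seeds, 1L)
  A <- .si_step_matrix(g)
  idx <- match(seeds, igraph::V(g)$name)
  if (!is.null(seed)) set.seed(seed)
  .si_run(A, beta, steps, idx)
}

#' Mean SI spread curve
#'
#' Averages `runs` independent trajectories from the same seed set. Each
#' run draws its RNG stream from a sub-seed derived deterministically from
#' `seed`, so results are reproducible and extending the run count leaves
#' earlier runs unchanged.
#'
#' @inheritParams simulate_si_once
#' @param runs number of independent repetitions (default 100).
#' @param seed master RNG seed.
#' @param keep_runs if `TRUE`, the per-run trajectory matrix is attached
#'   as attribute `"runs"`.
#' @return An object of class `spread_curve`: a data frame with columns
#'   `step` (0 ... steps) and `mean_infected`, with the simulation
#'   parameters as attributes.
#' @export
average_spread_curve <- function(g, beta, steps, seeds, runs = 100,
                                 seed = NULL, keep_runs = FALSE) {
  .check_graph(g)
  g <- .canonical_graph(g)
  seeds <- .check_si_params(g, beta, steps, seeds, runs)
  A <- .si_step_matrix(g)
  idx <- match(seeds, igraph::V(g)$name)
  traj <- vapply(seq_len(runs), function(r) {
    if (!is.null(seed)) set.seed(.derive_seed(seed, r))
    .si_run(A, beta, steps, idx)
  }, integer(steps + 1L))
  traj <- matrix(traj, nrow = steps + 1L)
  out <- data.frame(step = 0:steps, mean_infected = rowMeans(traj))
  attr(out, "beta") <- beta
  attr(out, "runs") <- NULL
  if (keep_runs) attr(out, "runs") <- traj
  attr(out, "seeds") <- seeds
  attr(out, "seed") <- seed
  class(out) <- c("spread_curve", "data.frame")
  out
}

#' Per-node spreading influence
#'
#' For each node, the mean infected count at the horizon when that node is
#' the sole initial seed — the SI-derived "standard ranking" of spreading
#' power against which centrality rankings are evaluated.
#'
#' @inheritParams average_spread_curve
#' @param beta infection probability (the benchmark experiments use 0.2).
#' @param steps horizon, in steps (default 10).
#' @return Named numeric vector over all nodes (canonical order); each
#'   entry lies in \[1, N\].
#' @export
single_seed_influence <- function(g, beta = 0.2, steps = 10, runs = 100,
                                  seed = NULL) {
  .check_graph(g)
  g <- .canonical_graph(g)
  stopifnot(beta >= 0, beta <= 1, steps >= 0, runs >= 1)
  A <- .si_step_matrix(g)
  ids <- igraph::V(g)$name
  infl <- vapply(seq_along(ids), function(i) {
    finals <- vapply(seq_len(runs), function(r) {
      if (!is.null(seed)) set.seed(.derive_seed(seed, (i - 1L) * runs + r))
      .si_run(A, beta, steps, i)[steps + 1L]
    }, integer(1))
    mean(finals)
  }, numeric(1))
  stats::setNames(infl, ids)
}

#' Heterogeneous mean-field epidemic threshold
#'
#' \eqn{\beta_{th} = \langle k \rangle / (\langle k^2 \rangle - \langle k
#' \rangle)}: the critical infection rate above which an outbreak reaches
#' a finite fraction of the network, from degree-based mean-field theory.
#'
#' @param stats a [node_statistics()] object or a graph.
#' @return The threshold, a positive number.
#' @export
epidemic_threshold <- function(stats) {
  if (igraph::is_igraph(stats)) stats <- node_statistics(stats)
  stopifnot(inherits(stats, "node_statistics"))
  k <- stats$nodes$degree
  if (length(k) == 0L || sum(k) == 0) {
    stop("epidemic threshold requires a graph with edges", call. = FALSE)
  }
  denom <- mean(k^2) - mean(k)
  if (denom <= 0) {
    stop("epidemic threshold undefined: <k^2> <= <k>", call. = FALSE)
  }
  mean(k) / denom
}
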