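test_that("degenerate infection rates give their closed-form trajectories", {
  g <- fig1()
  expect_equal(simulate_si_once(g, beta = 0, steps = 5, seeds = "3"),
               rep(1L, 6))
  # beta = 1 floods a connected graph within its diameter
  traj <- simulate_si_once(g, beta = 1, steps = 3, seeds = "2")
  expect_equal(traj[3:4], c(7L, 7L))
  path3 <- read_edgelist(c("a b", "b c"))
  expect_equal(simulate_si_once(path3, beta = 1, steps = 2, seeds = "a"),
               c(1L, 2L, 3L))
  expect_error(simulate_si_once(g, 0.2, 5, seeds = character(0)), "seed")
  expect_error(simulate_si_once(g, 0.2, 5, seeds = "99"), "unknown node")
})

test_that("trajectories are monotone, bounded, and start at the seed count", {
  g <- erdos_renyi_graph(60, 0.06, seed = 11)
  for (s in 1:5) {
    traj <- simulate_si_once(g, beta = 0.3, steps = 15,
                             seeds = c("1", "2"), seed = s)
    expect_equal(traj[1], 2L)
    expect_true(all(diff(traj) >= 0))
    expect_lte(max(traj), igraph::gorder(g))
  }
})

test_that("averaged curves are reproducible and honour the degenerate rates", {
  g <- fig1()
  c0 <- average_spread_curve(g, beta = 0, steps = 4, seeds = "1",
                             runs = 10, seed = 1)
  expect_equal(c0$mean_infected, rep(1, 5))
  c1 <- average_spread_curve(g, beta = 1, steps = 3, seeds = "1",
                             runs = 10, seed = 1)
  expect_equal(c1$mean_infected[2:4], rep(7, 3))

  ga <- erdos_renyi_graph(50, 0.08, seed = 5)
  a <- average_spread_curve(ga, 0.2, 10, seeds = "1", runs = 30, seed = 99)
  b <- average_spread_curve(ga, 0.2, 10, seeds = "1", runs = 30, seed = 99)
  expect_identical(a$mean_infected, b$mean_infected)
  # extending the run count preserves the earlier runs' trajectories
  r30 <- attr(average_spread_curve(ga, 0.2, 10, seeds = "1", runs = 30,
                                   seed = 99, keep_runs = TRUE), "runs")
  r40 <- attr(average_spread_curve(ga, 0.2, 10, seeds = "1", runs = 40,
                                   seed = 99, keep_runs = TRUE), "runs")
  expect_identical(r30, r40[, 1:30])
})

test_that("the averaged curve approaches a high-repetition reference", {
  g <- erdos_renyi_graph(100, 0.05, seed = 4)
  seed_node <- rank_nodes(degree_centrality(g), k = 1)$node
  lo <- average_spread_curve(g, 0.2, 6, seeds = seed_node, runs = 100, seed = 1)
  hi <- average_spread_curve(g, 0.2, 6, seeds = seed_node, runs = 2000, seed = 2)
  # binomial sampling error: mean of 100 draws bounded by N; 4 sigma margin
  se <- 4 * (igraph::gorder(g) / 2) / sqrt(100)
  expect_true(all(abs(lo$mean_infected - hi$mean_infected) < se))
})

test_that("single-seed influence hits its bounds and ranks the hub first", {
  g <- fig1()
  infl0 <- single_seed_influence(g, beta = 0, steps = 5, runs = 3, seed = 1)
  expect_true(all(infl0 == 1))
  infl1 <- single_seed_influence(g, beta = 1, steps = 3, runs = 3, seed = 1)
  expect_true(all(infl1 == igraph::gorder(g)))

  infl <- single_seed_influence(g, beta = 0.2, steps = 10, runs = 300, seed = 7)
  expect_true(all(infl >= 1 & infl <= igraph::gorder(g)))
  expect_equal(names(which.max(infl)), "1")
})

test_that("mean final infections grow with the infection rate", {
  g <- erdos_renyi_graph(50, 0.08, seed = 2)
  finals <- vapply(c(0, 0.1, 0.3, 0.6, 1), function(b) {
    cv <- average_spread_curve(g, b, steps = 8, seeds = "1",
                               runs = 60, seed = 123)
    cv$mean_infected[9]
  }, numeric(1))
  expect_true(all(diff(finals) >= 0))
})

test_that("the mean-field epidemic threshold matches its closed forms", {
  expect_equal(epidemic_threshold(toy_graphs()$complete5), 1 / 3)  # 1/(n-2)
  expect_equal(epidemic_threshold(toy_graphs()$cycle6), 1)         # 1/(k-1)
  expect_equal(epidemic_threshold(toy_graphs()$cube), 1 / 2)
  g <- erdos_renyi_graph(1000, 0.01, seed = 31)
  k <- mean(igraph::degree(g))
  expect_lt(abs(epidemic_threshold(g) - 1 / k), 0.02)
  expect_error(epidemic_threshold(read_edgelist("a b")), "undefined")
})
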