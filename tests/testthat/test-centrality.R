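test_that("traditional centralities match their closed forms and oracles", {
  star <- toy_graphs()$star5
  dc <- degree_centrality(star)$scores
  expect_equal(max(dc), 4)
  expect_equal(degree_centrality(fig1())$scores[["1"]], 6)

  path3 <- read_edgelist(c("a b", "b c"))
  expect_equal(betweenness_centrality(path3)$scores[["b"]], 1)
  expect_equal(betweenness_centrality(star)$scores[["1"]], choose(4, 2))
  for (s in 1:3) {
    g <- erdos_renyi_graph(18, 0.15, seed = s)
    expect_equal(betweenness_centrality(g)$scores, oracle_betweenness(g))
  }

  expect_true(all(closeness_centrality(toy_graphs()$complete5)$scores == 1))
  cc3 <- closeness_centrality(path3)$scores
  expect_equal(cc3[["b"]], 1)
  expect_equal(cc3[["a"]], 2 / 3)
  expect_equal(closeness_centrality(fig1())$scores[["1"]], 1)
  expect_warning(closeness_centrality(toy_graphs()$two_triangles),
                 "disconnected")

  expect_true(all(kshell_centrality(fig1())$scores == 2))
  expect_true(all(kshell_centrality(toy_graphs()$path5)$scores == 1))
  expect_true(all(kshell_centrality(toy_graphs()$complete5)$scores == 4))
})

test_that("gravity GM matches a brute-force double loop", {
  pair <- read_edgelist("a b")
  expect_equal(gravity_gm(pair, radius = 1)$scores, c(a = 1, b = 1))
  star <- toy_graphs()$star5
  expect_equal(gravity_gm(star, radius = 1)$scores[["1"]], 4 * 1 * 4)
  for (s in 1:3) {
    g <- erdos_renyi_graph(20, 0.15, seed = s)
    k <- as.numeric(igraph::degree(g))
    for (R in 1:2) {
      expect_equal(gravity_gm(g, radius = R)$scores,
                   oracle_hop_gravity(g, k, R))
    }
  }
})

test_that("EDGM sums degree products over squared effective distances", {
  pair <- read_edgelist("a b")
  expect_equal(gravity_edgm(pair)$scores, c(a = 1, b = 1))

  g <- fig1()
  D <- effective_distance_matrix(g)
  k <- stats::setNames(as.numeric(igraph::degree(g)), node_ids(g))
  manual <- sum(k["2"] * k[setdiff(node_ids(g), "2")] /
                  D["2", setdiff(node_ids(g), "2")]^2)
  expect_equal(gravity_edgm(g)$scores[["2"]], manual)

  # disconnected pairs contribute zero
  two <- toy_graphs()$two_triangles
  expect_equal(gravity_edgm(two)$scores[["1"]],
               sum(2 * 2 / effective_distance_matrix(two)["1", c("2", "3")]^2))
})

test_that("GGM reduces to GM at alpha = 0 and on triangle-free graphs", {
  for (s in 1:3) {
    g <- erdos_renyi_graph(25, 0.12, seed = s)
    expect_equal(gravity_ggm(g, alpha = 0)$scores, gravity_gm(g)$scores)
  }
  cube <- toy_graphs()$cube   # triangle-free: all C_i = 0
  expect_equal(gravity_ggm(cube, alpha = 3)$scores, gravity_gm(cube)$scores)

  tri <- read_edgelist(c("1 2", "2 3", "1 3"))
  s <- gravity_ggm(tri, radius = 1, alpha = 1)$scores
  expect_equal(unname(s), rep(2 * (exp(-1) * 2)^2, 3))
  expect_equal(gravity_ggm(tri, alpha = 2)$params$alpha, 2)
})

test_that("propagation capability reproduces the worked-example masses", {
  sp <- propagation_capability(fig1())
  expect_equal(sp[["2"]], exp(-1) * (2 / 6 + 2 / 2))
  expect_equal(round(sp[["2"]], 4), 0.4905)
  expect_equal(sp[["1"]], exp(-1 / 3) * (6 / 6 + 2 / 2))
  expect_equal(round(sp[["1"]], 4), 1.4331)
  expect_equal(unname(propagation_capability(toy_graphs()$cycle6)), rep(2, 6))
  iso <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(iso)$name <- c("a", "b", "c")
  expect_error(propagation_capability(iso), "edgeless")
})

test_that("pairwise attraction follows the gravity formula", {
  sp <- propagation_capability(fig1())
  expect_equal(round(pairwise_attraction(sp[["2"]], sp[["1"]], 2), 4), 0.1757)
  expect_equal(round(pairwise_attraction(sp[["2"]], sp[["5"]], 2), 4), 0.1240)
  expect_equal(pairwise_attraction(1.3, 0.7, Inf), 0)
  expect_error(pairwise_attraction(1, 1, 0))
})

test_that("LEDGM reproduces the published seven-node scores", {
  scores <- ledgm(fig1())$scores
  expect_equal(round(scores[["2"]], 4), 0.2997)
  ref <- fig1_table1()
  expect_lt(max(abs(scores[names(ref$ledgm)] - ref$ledgm)), 5e-5)
  expect_equal(ledgm(fig1())$params$radius, 1)
})

test_that("the unrestricted variant matches its published row and the R >= diameter identity", {
  g <- fig1()
  un <- ledgm_unrestricted(g)$scores
  ref <- fig1_table1()
  # published values are truncated to 4 decimals, so compare at one ulp
  expect_lt(max(abs(un[names(ref$rledgm)] - ref$rledgm)), 1e-4)
  # node 1's influence set already spans the network: scores coincide
  expect_equal(ledgm(g)$scores[["1"]], un[["1"]])

  pair <- read_edgelist("a b")
  expect_equal(ledgm(pair)$scores, ledgm_unrestricted(pair)$scores)

  for (s in 1:3) {
    h <- random_connected_graph(15, 0.2, seed = 5 * s)
    expect_equal(ledgm(h, radius = graph_diameter(h))$scores,
                 ledgm_unrestricted(h)$scores)
  }
  expect_error(ledgm(igraph::make_empty_graph(2, directed = FALSE)))
})

test_that("vertex-transitive graphs score uniformly under every method", {
  for (g in list(toy_graphs()$cycle6, toy_graphs()$complete5)) {
    for (m in c("dc", "bc", "cc", "ks", "gm", "edgm", "ggm", "ledgm", "rledgm")) {
      s <- node_centrality(g, m)$scores
      expect_lt(diff(range(s)), 1e-12)
    }
  }
})

test_that("rankings sort by score with ascending-id tie-breaks", {
  r <- rank_nodes(ledgm(fig1()))
  expect_equal(r$node, c("1", "4", "5", "6", "2", "3", "7"))
  expect_equal(rank_nodes(ledgm(fig1()), k = 1)$node, "1")

  tied <- degree_centrality(toy_graphs()$cycle6)
  expect_equal(rank_nodes(tied)$node, as.character(1:6))

  # numeric-aware tie-break: "10" ranks after "2"
  g10 <- read_edgelist(c("2 10", "10 2"))
  expect_equal(rank_nodes(degree_centrality(g10))$node, c("2", "10"))

  expect_warning(r2 <- rank_nodes(ledgm(fig1()), k = 99), "truncated")
  expect_equal(nrow(r2), 7)
})
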