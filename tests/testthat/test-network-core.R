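test_that("edge lists round-trip and dirty input is cleaned", {
  g <- read_edge_list(edge_file(c("# comment", "0 1", "1 2")))
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)

  expect_message(
    g2 <- read_edge_list(edge_file(c("0 0", "0 1"))),
    "dropped")
  expect_equal(igraph::vcount(g2), 2L)
  expect_equal(igraph::ecount(g2), 1L)

  expect_message(
    g3 <- read_edge_list(edge_file(c("0 1", "1 0"))),
    "dropped")
  expect_equal(igraph::ecount(g3), 1L)

  expect_error(read_edge_list(edge_file(c("0 1", "a 2"))), "line 2")
  expect_error(read_edge_list(tempfile()), "not found")

  # write-then-read is the identity on node and edge sets (isolated
  # nodes cannot appear in the two-column format, so none are present)
  g4 <- rand_graph(25, 0.15, seed = 3)
  g4 <- igraph::delete_vertices(g4, igraph::V(g4)[igraph::degree(g4) == 0])
  f <- tempfile()
  write_edge_list(g4, f)
  g5 <- read_edge_list(f)
  expect_setequal(igraph::V(g5)$name, igraph::V(g4)$name)
  canon <- function(g) {
    el <- apply(igraph::as_edgelist(g, names = TRUE), 2L, as.integer)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(canon(g5), canon(g4))
})

test_that("degree moments match their definitions", {
  tri <- named_graph(igraph::make_full_graph(3))
  expect_equal(mean_degree(tri), 2)
  expect_equal(mean_squared_degree(tri), 4)

  star <- named_graph(igraph::make_star(5, mode = "undirected"))
  expect_equal(mean_squared_degree(star), 4)

  g <- rand_graph(5, 0.5, seed = 9)
  expect_equal(mean_squared_degree(g), mean(igraph::degree(g)^2))
  expect_equal(mean_degree(g) * igraph::vcount(g), 2 * igraph::ecount(g))

  empty <- named_graph(igraph::make_empty_graph(0, directed = FALSE), ids = integer(0))
  expect_error(mean_degree(empty), "empty")
})

test_that("local clustering matches exhaustive triangle counting", {
  tri <- named_graph(igraph::make_full_graph(3))
  expect_equal(local_clustering(tri, 1), 1)
  star <- named_graph(igraph::make_star(6, mode = "undirected"))
  expect_equal(local_clustering(star, 1), 0)

  g <- rand_graph(6, 0.6, seed = 21)
  for (u in igraph::V(g)$name) {
    expect_equal(local_clustering(g, u), naive_local_clustering(g, u),
                 info = paste("node", u))
  }
  expect_true(clustering_coefficient(g) >= 0 && clustering_coefficient(g) <= 1)
})

test_that("core decomposition agrees with naive iterative pruning", {
  k4 <- named_graph(igraph::make_full_graph(4))
  expect_true(all(core_decomposition(k4) == 3L))
  star <- named_graph(igraph::make_star(7, mode = "undirected"))
  expect_true(all(core_decomposition(star) == 1L))

  # K4 plus a pendant path
  g <- read_edge_list(edge_file(c("1 2", "1 3", "1 4", "2 3", "2 4", "3 4",
                                  "4 5", "5 6", "6 7", "7 8")))
  expect_identical(core_decomposition(g), naive_coreness(g))

  for (s in 1:8) {
    g <- rand_graph(sample(8:30, 1), 0.2, seed = 100 + s)
    expect_identical(core_decomposition(g), naive_coreness(g),
                     info = paste("seed", 100 + s))
  }
})

test_that("modularity reproduces the hand formula and its invariances", {
  tt <- generate_planted_cliques(2, 3, bridges = 0)
  expect_equal(modularity_q(tt$graph, tt$membership), 0.5)
  expect_equal(modularity_q(tt$graph, tt$membership),
               hand_modularity(tt$graph, tt$membership))

  one <- setNames(rep(0L, 6), igraph::V(tt$graph)$name)
  expect_equal(modularity_q(tt$graph, one), 0)

  # invariant under community relabeling; always within [-1/2, 1]
  g <- rand_graph(20, 0.2, seed = 5)
  set.seed(6)
  memb <- setNames(sample(1:4, 20, replace = TRUE), igraph::V(g)$name)
  q <- modularity_q(g, memb)
  expect_equal(modularity_q(g, setNames(memb * 10 + 3, names(memb))), q)
  expect_equal(q, hand_modularity(g, memb))
  expect_true(q >= -0.5 && q <= 1)

  expect_error(modularity_q(g, memb[-1]), "cover")
})

test_that("power-law exponent estimator recovers a known exponent", {
  # graph with an exact heavy-tailed degree sequence (multigraph is fine:
  # only degrees enter the estimator)
  set.seed(77)
  # discrete power law alpha = 2.5, k >= 5 (continuity-corrected rounding)
  k <- floor(4.5 * runif(10000)^(-1 / 1.5) + 0.5)
  if (sum(k) %% 2 == 1) k[1] <- k[1] + 1
  g <- named_graph(igraph::sample_degseq(k))
  expect_lt(abs(power_law_exponent(g) - 2.5), 0.1)

  reg <- named_graph(igraph::make_ring(20))
  expect_warning(a <- power_law_exponent(reg), "degenerate")
  expect_true(is.na(a))

  twopoint <- named_graph(igraph::make_star(11, mode = "undirected"))
  expect_warning(a2 <- power_law_exponent(twopoint), NA)
  expect_true(is.finite(a2) && a2 > 1)
})

test_that("graph_stats collects the summary columns coherently", {
  kar <- zachary_karate()
  p <- louvain_one_pass(kar)
  st <- graph_stats(kar, p)
  expect_equal(st$n, 34L)
  expect_equal(st$m, 78L)
  expect_equal(round(st$mean_degree, 2), 4.59)
  expect_equal(st$max_coreness, max(core_decomposition(kar)))
  expect_gte(st$mean_sq_degree, st$mean_degree^2)  # Jensen
  expect_equal(st$modularity, modularity_q(kar, p))
})
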