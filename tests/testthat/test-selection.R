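test_that("the toy-network sweep picks node 3 then node 7", {
  fx <- fig1_fixture()
  sc <- degree_centrality(fx$graph)
  s <- select_supernode(fx$graph, fx$partition, sc, 2)
  expect_identical(as.integer(s), c(3L, 7L))
  # after the first pick everything except node 7 is off-limits
  expect_identical(ineligible_nodes(fx$graph, fx$partition, 3L),
                   c(1L, 2L, 4L, 5L, 6L, 8L, 9L, 10L))
  # k = 1 degenerates to the top of the largest super node
  expect_identical(as.integer(select_supernode(fx$graph, fx$partition, sc, 1)), 3L)
})

test_that("disconnected communities each contribute one spreader", {
  tt <- generate_planted_cliques(2, 3, bridges = 0)
  sc <- degree_centrality(tt$graph)
  s <- select_supernode(tt$graph, tt$partition, sc, 2)
  expect_identical(as.integer(s), c(1L, 4L))  # degree ties, lowest ids
})

test_that("sweep-1 exclusion invariants hold on synthetic networks", {
  for (sd in c(3, 8)) {
    net <- generate_lfr(n = 1200, seed = sd, c_min = 25)
    g <- net$graph
    p <- louvain_one_pass(g)
    sc <- degree_centrality(g)
    k <- min(15L, p$l %/% 2L)
    s <- select_supernode(g, p, sc, k)
    expect_length(unique(as.integer(s)), k)
    # at most one spreader per super node in sweep 1
    sn <- p$membership[as.character(as.integer(s))]
    expect_equal(anyDuplicated(sn), 0L)
    # exclusion rule: each spreader has no edge into the super nodes
    # that contained a spreader at the moment it was picked
    for (i in seq_along(s)) {
      if (i == 1L) next
      mem <- unlist(p$members[as.character(sn[seq_len(i - 1L)])],
                    use.names = FALSE)
      nbrs <- as.integer(igraph::V(g)$name[as.integer(
        igraph::neighbors(g, as.character(as.integer(s)[i])))])
      expect_length(intersect(nbrs, mem), 0L)
    }
    # consequently no two sweep-1 spreaders are adjacent
    for (i in seq_along(s)) for (j in seq_along(s)) {
      if (i < j) expect_false(igraph::are_adjacent(
        g, as.character(as.integer(s)[i]), as.character(as.integer(s)[j])))
    }
    # deterministic
    expect_identical(as.integer(select_supernode(g, p, sc, k)), as.integer(s))
  }
})

test_that("later sweeps relax the exclusion rule instead of deadlocking", {
  tt <- generate_planted_cliques(2, 4, bridges = 0)
  sc <- degree_centrality(tt$graph)
  s <- select_supernode(tt$graph, tt$partition, sc, 6)
  expect_length(s, 6L)
  expect_equal(anyDuplicated(as.integer(s)), 0L)
  # sweep 1 takes one per clique; relaxed sweeps fill from both
  expect_identical(as.integer(s)[1:2], c(1L, 5L))
  expect_error(select_supernode(tt$graph, tt$partition, sc, 9), "k must")
})

test_that("top-k selection matches a full sort", {
  star <- igraph::add_vertices(
    named_graph(igraph::make_star(6, mode = "undirected")), 2,
    name = c("7", "8"))
  sc <- degree_centrality(star)
  expect_identical(as.integer(select_influential(star, sc, 1)), 1L)
  expect_length(select_influential(star, sc, 8), 8L)
  expect_error(select_influential(star, sc, 9), "k must")

  g <- rand_graph(20, 0.3, seed = 17)
  sc <- degree_centrality(g)
  ids <- as.integer(names(sc))
  oracle <- ids[order(-as.numeric(sc), ids)][1:5]
  expect_identical(as.integer(select_influential(g, sc, 5)), oracle)
})

test_that("the unconnected greedy walk matches its oracle and reports shortfall", {
  path3 <- read_edge_list(edge_file(c("0 1", "1 2")))
  sc <- degree_centrality(path3)
  expect_error(select_disperse(path3, sc, 2), "shortfall.*only 1")

  two_edges <- read_edge_list(edge_file(c("0 1", "2 3")))
  s <- select_disperse(two_edges, degree_centrality(two_edges), 2)
  expect_identical(as.integer(s), c(0L, 2L))

  for (sd in c(23, 29)) {
    g <- rand_graph(30, 0.15, seed = sd)
    sc <- degree_centrality(g)
    expect_identical(as.integer(select_disperse(g, sc, 5)),
                     oracle_disperse(g, sc, 5))
  }
  # accepted sets are always mutually unconnected
  g <- rand_graph(40, 0.1, seed = 31)
  s <- select_disperse(g, degree_centrality(g), 6)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_false(igraph::are_adjacent(g, as.character(as.integer(s)[i]),
                                      as.character(as.integer(s)[j])))
  }
})

test_that("spreader files carry a manifest header", {
  fx <- fig1_fixture()
  s <- select_supernode(fx$graph, fx$partition, degree_centrality(fx$graph), 2)
  f <- tempfile()
  write_spreaders(s, f, extra = c(seed = 1))
  lines <- readLines(f)
  expect_true(any(grepl("method: supernode", lines)))
  expect_identical(lines[!grepl("^#", lines)], c("3", "7"))
})
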