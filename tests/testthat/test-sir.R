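test_that("parameter constructor enforces the lambda-beta-mu relation", {
  p <- sir_params(lam = 1.5, beta = 0.2)
  expect_equal(p$mu, 0.3)
  p2 <- sir_params(mu = 0.3, beta = 0.2)
  expect_equal(p2$lam, 1.5)
  expect_error(sir_params(lam = 10, beta = 0.5), "\\[0, 1\\]")
  expect_error(sir_params(beta = 0.5), "two of")
  kar <- zachary_karate()
  auto <- auto_sir_params(kar, lam = 1.5)
  expect_equal(auto$beta, 1 / mean_degree(kar))
  expect_equal(auto$mu, 1.5 / mean_degree(kar))
})

test_that("without transmission the final size is exactly the seed set", {
  kar <- zachary_karate()
  pars <- sir_params(mu = 0, beta = 0.3, runs = 50, seed = 1)
  out <- influence_scope(kar, c(1L, 34L), pars)
  expect_equal(out$influence_scope, 2 / 34)
  expect_equal(var(out$final_fractions), 0)
})

test_that("tiny networks reproduce the enumerable closed forms", {
  # single edge, certain transmission and recovery: everyone ever infected
  edge <- read_edge_list(edge_file("1 2"))
  pars <- sir_params(mu = 1, beta = 1, runs = 40, seed = 2)
  out <- influence_scope(edge, 1L, pars)
  expect_true(all(out$final_fractions == 1))

  # path A-B-C seeded at A: B always infected; B's one contact hits C
  # with probability 1/2, so E[final fraction] = (2/3 + 1)/2 = 5/6
  path3 <- read_edge_list(edge_file(c("1 2", "2 3")))
  pars <- sir_params(mu = 1, beta = 1, runs = 4000, seed = 3)
  out <- influence_scope(path3, 1L, pars)
  se <- (1 / 6) / sqrt(4000)
  expect_lt(abs(out$influence_scope - 5 / 6), 3 * se)
  expect_true(all(out$final_fractions %in% c(2 / 3, 1)))

  # star seeded at the hub with certain recovery: the hub transmits to
  # exactly one leaf, so the final fraction is always 2/n
  star <- named_graph(igraph::make_star(7, mode = "undirected"))
  out <- influence_scope(star, 1L, sir_params(mu = 1, beta = 1,
                                              runs = 30, seed = 4))
  expect_true(all(out$final_fractions == 2 / 7))
})

test_that("states are conserved and move only along S -> I -> R", {
  kar <- zachary_karate()
  pars <- auto_sir_params(kar, lam = 1.5, seed = 11)
  res <- sir_run(kar, 34L, pars, trace = TRUE)
  tr <- attr(res, "trace")
  expect_true(all(rowSums(tr) == 34))
  expect_true(all(diff(tr[, "R"]) >= 0))   # recovered never shrinks
  expect_true(all(diff(tr[, "S"]) <= 0))   # susceptible never grows
  expect_equal(tr[nrow(tr), "I"], c(I = 0L))
  expect_equal(res[1], tr[nrow(tr), "R"] / 34, ignore_attr = TRUE)

  # isolated seed can only recover
  iso <- igraph::add_vertices(kar, 1, name = "35")
  expect_equal(sir_run(iso, 35L, sir_params(mu = 1, beta = 1, seed = 1)),
               1 / 35)
  expect_error(sir_run(kar, 99L, pars), "not present")
})

test_that("influence scope is monotone in the transmission probability", {
  kar <- zachary_karate()
  mus <- c(0.1, 0.3, 0.6, 0.9)
  # common random numbers: identical replicate seeds across mu values
  scopes <- vapply(mus, function(m) {
    influence_scope(kar, 34L, sir_params(mu = m, beta = 0.3,
                                         runs = 1500, seed = 77))$influence_scope
  }, numeric(1))
  expect_true(all(diff(scopes) > -0.01))
  expect_gt(scopes[4], scopes[1])
})

test_that("replicates stream from the master seed reproducibly", {
  kar <- zachary_karate()
  pars <- auto_sir_params(kar, lam = 1.1, runs = 25, seed = 123)
  a <- influence_scope(kar, c(1L, 34L), pars)
  b <- influence_scope(kar, c(1L, 34L), pars)
  expect_identical(a$final_fractions, b$final_fractions)
  # extending the run count preserves the earlier replicates
  pars2 <- auto_sir_params(kar, lam = 1.1, runs = 40, seed = 123)
  c40 <- influence_scope(kar, c(1L, 34L), pars2)
  expect_identical(c40$final_fractions[1:25], a$final_fractions)
  f <- tempfile()
  write_outcome(a, f)
  expect_true(grepl("influence_scope", readLines(f)[1]))
})
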