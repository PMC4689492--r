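# Fixture builders and independent oracles used across the suite.

# igraph graph with original-id names attached (the package convention)
named_graph <- function(g, ids = seq_len(igraph::vcount(g))) {
  igraph::V(g)$name <- as.character(ids)
  g
}

rand_graph <- function(n, p, seed) {
  set.seed(seed)
  named_graph(igraph::sample_gnp(n, p))
}

edge_file <- function(lines) {
  f <- tempfile(fileext = ".edges")
  writeLines(lines, f)
  f
}

zachary_karate <- function() named_graph(igraph::make_graph("Zachary"))

# --- independent oracles -------------------------------------------------

# coreness by literal iterative pruning (no igraph)
naive_coreness <- function(g) {
  ids <- as.integer(igraph::V(g)$name)
  el <- apply(igraph::as_edgelist(g, names = TRUE), 2L, as.integer)
  if (length(el) == 0L) el <- matrix(integer(0), 0L, 2L)
  core <- setNames(rep(0L, length(ids)), as.character(ids))
  alive <- rep(TRUE, length(ids))
  k <- 0L
  while (any(alive)) {
    repeat {
      deg <- setNames(rep(0L, length(ids)), as.character(ids))
      keep <- alive[match(el[, 1L], ids)] & alive[match(el[, 2L], ids)]
      for (r in which(keep)) {
        deg[as.character(el[r, 1L])] <- deg[as.character(el[r, 1L])] + 1L
        deg[as.character(el[r, 2L])] <- deg[as.character(el[r, 2L])] + 1L
      }
      victim <- alive & deg < k
      if (!any(victim)) break
      alive[victim] <- FALSE
    }
    core[alive] <- k
    k <- k + 1L
  }
  core
}

# Newman-Girvan Q evaluated directly from its definition
hand_modularity <- function(g, membership) {
  el <- igraph::as_edgelist(g, names = TRUE)
  m <- nrow(el)
  comms <- unique(membership)
  q <- 0
  deg <- igraph::degree(g)
  names(deg) <- igraph::V(g)$name
  for (cc in comms) {
    inside <- names(membership)[membership == cc]
    e_c <- sum(el[, 1L] %in% inside & el[, 2L] %in% inside)
    d_c <- sum(deg[inside])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# brute-force local clustering by triangle enumeration
naive_local_clustering <- function(g, u) {
  nb <- igraph::V(g)$name[as.integer(igraph::neighbors(g, as.character(u)))]
  d <- length(nb)
  if (d < 2L) return(0)
  tri <- 0L
  for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
    if (igraph::are_adjacent(g, nb[i], nb[j])) tri <- tri + 1L
  }
  tri / (d * (d - 1) / 2)
}

# independent reimplementation of the unconnected-top-k greedy walk,
# working on the dense adjacency matrix
oracle_disperse <- function(g, scores, k) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  ids <- as.integer(rownames(A))
  ranking <- ids[order(-as.numeric(scores)[match(as.character(ids), names(scores))], ids)]
  picked <- integer(0)
  for (id in ranking) {
    if (length(picked) &&
        any(A[as.character(id), as.character(picked)] > 0)) next
    picked <- c(picked, id)
    if (length(picked) == k) break
  }
  picked
}

# exhaustive check that no single node can move to a neighbouring
# community with a strictly positive modularity gain
is_node_move_optimal <- function(g, partition) {
  memb <- partition$membership
  q0 <- modularity_q(g, memb)
  for (v in names(memb)) {
    nbc <- unique(memb[igraph::V(g)$name[
      as.integer(igraph::neighbors(g, v))]])
    for (cc in setdiff(nbc, memb[v])) {
      alt <- memb
      alt[v] <- cc
      if (modularity_q(g, alt) > q0 + 1e-9) return(FALSE)
    }
  }
  TRUE
}
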