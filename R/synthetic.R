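#' Generate an LFR-style benchmark network
#'
#' Self-contained configuration-model construction of a network with
#' power-law degrees (exponent `tau1`, minimum degree `k_min`, maximum
#' degree solved from the target mean degree `k_avg`), power-law planted
#' community sizes (exponent `tau2`, range `[c_min, c_max]`), and a mixing
#' parameter `mu`: each node places a fraction ~`mu` of its edge stubs
#' outside its own community.  Internal stubs are matched within each
#' community and external stubs globally (never joining two nodes of the
#' same community); invalid pairings (loops, duplicates) are re-shuffled
#' for a bounded number of rounds and any leftover stubs are dropped, so
#' realized degrees can fall slightly below their targets.
#'
#' Defaults emulate the LFR1 study conditions: n = 10^4, tau1 = tau2 =
#' 2.5, mu = 0.1, k_min = 5, mean degree ~13.07, and a community-size
#' range yielding roughly 150-160 planted communities.
#'
#' @param n Number of nodes (ids `1..n`).
#' @param tau1 Degree-distribution exponent (> 2 for a finite mean here).
#' @param tau2 Community-size exponent.
#' @param mu Mixing parameter in `[0, 1]`.
#' @param k_min Minimum degree.
#' @param k_avg Target mean degree; the degree cutoff `k_max` is solved
#'   numerically from it when not supplied.
#' @param k_max Optional explicit degree cutoff.
#' @param c_min,c_max Community-size range.  `c_max = NULL` (default)
#'   uses `max(n/10, k_max + 1)` so that the largest hubs can always be
#'   hosted; a user-supplied `c_max` instead caps `k_max` accordingly.
#' @param seed Integer seed.
#' @param max_retries Bounded retries for infeasible size/assignment draws.
#' @return A list: `graph` (igraph, vertex names `1..n`), `partition`
#'   (`supernode_partition` of the planted communities), `membership`
#'   (named vector), `params`, and `realized` (mean degree, mixing,
#'   community count).
#' @export
generate_lfr <- function(n = 10000L, tau1 = 2.5, tau2 = 2.5, mu = 0.1,
                         k_min = 5L, k_avg = 13.07, k_max = NULL,
                         c_min = 25L, c_max = NULL, seed = NULL,
                         max_retries = 20L) {
  stopifnot(tau1 > 1, tau2 > 1, mu >= 0, mu <= 1, k_min >= 1, k_avg >= k_min,
            c_min >= 2, n > c_min)
  with_seed(seed, {
    if (is.null(k_max)) k_max <- solve_plaw_cutoff(tau1, k_min, k_avg)
    if (!is.null(c_max) && mu < 1) {
      # hubs must fit their internal degree inside the largest community
      k_max <- min(k_max, floor((c_max - 1) / (1 - mu)))
    }
    k_max <- min(k_max, n - 1L)
    if (is.null(c_max)) c_max <- max(round(n / 10), k_max + 1L)
    stopifnot(c_max >= c_min)

    # continuous sampling on [k_min - 1/2, k_max + 1/2] then rounding
    # approximates the discrete power law P(k) proportional to k^-tau1
    deg <- round(sample_trunc_plaw(n, tau1, k_min - 0.5, k_max + 0.5))
    deg <- pmin(pmax(deg, k_min), k_max)

    # internal/external split: floor + Bernoulli on the fraction keeps the
    # expectation exactly (1-mu)*k
    di <- floor((1 - mu) * deg)
    frac <- (1 - mu) * deg - di
    di <- as.integer(di + (stats::runif(n) < frac))
    di <- pmin(di, deg)

    for (attempt in seq_len(max_retries)) {
      sizes <- draw_community_sizes(n, tau2, c_min, c_max)
      need <- max(di) + 1L
      if (max(sizes) < need) sizes <- grow_largest(sizes, need, c_min)
      comm <- assign_communities(di, sizes)
      if (!is.null(comm)) break
      if (attempt == max_retries) {
        stop("could not realize a feasible community assignment after ",
             max_retries, " retries", call. = FALSE)
      }
    }
    sizes <- tabulate(comm)
    di <- pmin(di, sizes[comm] - 1L)
    de <- deg - di

    edges <- matrix(integer(0), 0L, 2L)
    # internal matching, one community at a time
    for (c_id in seq_along(sizes)) {
      mem <- which(comm == c_id)
      if (sum(di[mem]) %% 2L == 1L) {
        # drop one stub from the largest-internal-degree member; at mu > 0
        # it is rebooked as an external stub so the degree is kept
        v <- mem[which.max(di[mem])]
        di[v] <- di[v] - 1L
        if (mu > 0) de[v] <- de[v] + 1L
      }
      edges <- rbind(edges, wire_community(mem, di[mem], n))
    }
    # external matching, global, same-community pairs forbidden
    ext_stubs <- rep.int(seq_len(n), de)
    if (length(ext_stubs) %% 2L == 1L) ext_stubs <- ext_stubs[-length(ext_stubs)]
    if (length(ext_stubs)) {
      edges <- rbind(edges, match_stubs(ext_stubs, n, comm = comm,
                                        existing = edges))
    }

    g <- graph_from_edges(edges[, 1L], edges[, 2L])
    # nodes that lost every stub would vanish from the edge list; keep them
    missing <- setdiff(as.character(seq_len(n)), igraph::V(g)$name)
    if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)

    memb <- comm - 1L
    names(memb) <- as.character(seq_len(n))
    vdeg <- igraph::degree(g)[as.character(seq_len(n))]
    el <- igraph::as_edgelist(g, names = TRUE)
    ext_edges <- sum(memb[el[, 1L]] != memb[el[, 2L]])
    list(
      graph = g,
      partition = new_supernode_partition(memb),
      membership = memb,
      params = list(n = n, tau1 = tau1, tau2 = tau2, mu = mu, k_min = k_min,
                    k_avg = k_avg, k_max = k_max, c_min = c_min, c_max = c_max,
                    seed = seed),
      realized = list(mean_degree = mean(vdeg),
                      mixing = if (igraph::ecount(g) > 0)
                        ext_edges / igraph::ecount(g) else 0,
                      n_communities = length(sizes))
    )
  })
}

# Inverse-CDF sampling of a continuous truncated power law on [xmin, xmax].
sample_trunc_plaw <- function(n, tau, xmin, xmax) {
  a <- 1 - tau
  u <- stats::runif(n)
  (xmin^a + u * (xmax^a - xmin^a))^(1 / a)
}

# Integer cutoff kmax giving the rounded-continuous (= approximately
# discrete) truncated power law the requested mean.
solve_plaw_cutoff <- function(tau, kmin, target_mean) {
  a <- kmin - 0.5
  mean_at <- function(b) {
    if (abs(tau - 2) < 1e-9) (b - a) / log(b / a)
    else ((tau - 1) / (tau - 2)) *
      (a^(2 - tau) - b^(2 - tau)) / (a^(1 - tau) - b^(1 - tau))
  }
  upper <- if (tau > 2) a * ((tau - 1) / (tau - 2)) else Inf
  if (target_mean >= upper * 0.999) {
    stop("requested mean degree ", target_mean, " unreachable with k_min = ",
         kmin, " and tau1 = ", tau, " (supremum ", round(upper, 2), ")",
         call. = FALSE)
  }
  ceiling(stats::uniroot(function(b) mean_at(b) - target_mean,
                         lower = kmin + 1, upper = 1e8)$root - 0.5)
}

# Power-law community sizes summing exactly to n.
draw_community_sizes <- function(n, tau2, c_min, c_max) {
  sizes <- integer(0)
  while (sum(sizes) < n) {
    batch <- round(sample_trunc_plaw(32L, tau2, c_min, c_max))
    sizes <- c(sizes, pmin(pmax(batch, c_min), c_max))
  }
  sizes <- sizes[cumsum(sizes) - sizes < n]     # keep prefix reaching n
  excess <- sum(sizes) - n
  i <- length(sizes)
  while (excess > 0L && i >= 1L) {
    take <- min(excess, sizes[i] - c_min)
    sizes[i] <- sizes[i] - take
    excess <- excess - take
    i <- i - 1L
  }
  if (excess > 0L) {                            # all at c_min: drop one, pad largest
    sizes <- sizes[-length(sizes)]
    sizes[which.max(sizes)] <- sizes[which.max(sizes)] + (c_min - excess)
  }
  sizes
}

# Enlarge the largest community to `need` nodes, shrinking the smallest
# communities (respecting c_min; dropping one if necessary).
grow_largest <- function(sizes, need, c_min) {
  deficit <- need - max(sizes)
  j <- which.max(sizes)
  sizes[j] <- need
  ord <- order(sizes)
  for (i in ord) {
    if (deficit <= 0L) break
    if (i == j) next
    take <- min(deficit, sizes[i] - c_min)
    sizes[i] <- sizes[i] - take
    deficit <- deficit - take
  }
  if (deficit > 0L) {
    drop <- setdiff(order(sizes), j)[1L]
    deficit <- deficit - sizes[drop]
    sizes <- sizes[-drop]
    if (deficit < 0L) {
      j <- which.max(sizes)
      sizes[j] <- sizes[j] - deficit              # give back the overshoot
    }
  }
  sizes[sizes >= c_min | sizes > 0]
}

# Assign nodes to communities: internal degree must fit (size > d_int),
# capacity-weighted random choice; NULL when stuck (caller retries).
assign_communities <- function(di, sizes) {
  n <- length(di)
  cap <- sizes
  comm <- integer(n)
  for (v in order(di, decreasing = TRUE)) {
    ok <- which(cap > 0L & sizes > di[v])
    if (!length(ok)) return(NULL)
    c_id <- if (length(ok) == 1L) ok else ok[sample.int(length(ok), 1L, prob = cap[ok])]
    comm[v] <- c_id
    cap[c_id] <- cap[c_id] - 1L
  }
  comm
}

# Internal edges of one community.  Members whose internal degree nearly
# saturates the community (config-model collisions would be pathological)
# are wired directly to a budget-weighted sample of distinct partners;
# everyone else goes through random stub matching.
wire_community <- function(mem, d, n) {
  s <- length(mem)
  if (s < 2L || sum(d) == 0L) return(matrix(integer(0), 0L, 2L))
  keyf <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
  res <- d
  ea <- integer(0); eb <- integer(0); keys <- numeric(0)
  for (i in order(-res)) {
    if (res[i] < 0.6 * (s - 1)) break
    if (res[i] <= 0L) next
    cand <- setdiff(which(res > 0L), i)
    if (length(keys)) cand <- cand[!(keyf(mem[i], mem[cand]) %in% keys)]
    take <- min(res[i], length(cand))
    if (take > 0L) {
      sel <- if (length(cand) == take) cand
             else sample(cand, take, prob = res[cand])
      ea <- c(ea, rep.int(mem[i], take)); eb <- c(eb, mem[sel])
      keys <- c(keys, keyf(mem[i], mem[sel]))
      res[sel] <- res[sel] - 1L
      res[i] <- res[i] - take
    }
    res[i] <- 0L                       # unplaceable surplus is dropped
  }
  direct <- cbind(ea, eb, deparse.level = 0)
  rbind(direct, match_stubs(rep.int(mem, res), n, existing = direct))
}

# Random stub matching into unique simple edges.  Invalid pairs (loops,
# duplicates, forbidden same-community pairs) are re-shuffled for a
# bounded number of rounds; remaining stubs are then placed by
# degree-preserving edge swaps where possible, and only truly
# unplaceable stubs are dropped.
match_stubs <- function(stubs, n, comm = NULL, existing = NULL,
                        rounds = 40L) {
  keyf <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
  keys <- if (!is.null(existing) && nrow(existing))
    keyf(existing[, 1L], existing[, 2L]) else numeric(0)
  n_ext <- length(keys)                      # untouchable foreign edges
  kenv <- new.env(hash = TRUE, parent = emptyenv())   # O(1) duplicate lookup
  for (k0 in keys) assign(as.character(k0), TRUE, envir = kenv)
  out_a <- integer(0); out_b <- integer(0)
  for (r in seq_len(rounds)) {
    if (length(stubs) < 2L) break
    s <- sample(stubs)
    half <- length(s) %/% 2L
    a <- s[seq_len(half)]
    b <- s[half + seq_len(half)]
    k <- keyf(a, b)
    bad <- a == b | duplicated(k) | k %in% keys
    if (!is.null(comm)) bad <- bad | comm[a] == comm[b]
    keys <- c(keys, k[!bad])
    for (k0 in k[!bad]) assign(as.character(k0), TRUE, envir = kenv)
    out_a <- c(out_a, a[!bad]); out_b <- c(out_b, b[!bad])
    leftover <- c(a[bad], b[bad], if (length(s) %% 2L) s[length(s)])
    if (length(leftover) == length(stubs) && r > 5L) break   # stalled
    stubs <- leftover
  }
  # Repair: place each leftover stub pair (u, v); when the direct edge is
  # invalid, swap with an accepted edge (x, y): replace it by (u, x) and
  # (v, y), which preserves the degrees of x and y.
  ok_pair <- function(p, q) {
    p != q && !exists(as.character(keyf(p, q)), envir = kenv) &&
      (is.null(comm) || comm[p] != comm[q])
  }
  add_edge <- function(p, q) {
    keys <<- c(keys, keyf(p, q))
    assign(as.character(keyf(p, q)), TRUE, envir = kenv)
    out_a <<- c(out_a, p); out_b <<- c(out_b, q)
  }
  drop_edge <- function(e) {               # e indexes out_a/out_b
    rm(list = as.character(keys[n_ext + e]), envir = kenv)
    keys <<- keys[-(n_ext + e)]
    out_a <<- out_a[-e]; out_b <<- out_b[-e]
  }
  while (length(stubs) >= 2L) {
    u <- stubs[1L]; v <- stubs[2L]; stubs <- stubs[-(1:2)]
    if (ok_pair(u, v)) {
      add_edge(u, v)
      next
    }
    placed <- FALSE
    ne <- length(out_a)
    if (ne > 0L) {
      cand <- sample.int(ne, min(ne, 300L))
      for (e in cand) {
        x <- out_a[e]; y <- out_b[e]
        if (ok_pair(u, x) && ok_pair(v, y) && keyf(u, x) != keyf(v, y)) {
          drop_edge(e); add_edge(u, x); add_edge(v, y)
          placed <- TRUE
          break
        }
        if (ok_pair(u, y) && ok_pair(v, x) && keyf(u, y) != keyf(v, x)) {
          drop_edge(e); add_edge(u, y); add_edge(v, x)
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) stubs <- c(stubs, u)      # v's stub is dropped; retry u
  }
  cbind(out_a, out_b, deparse.level = 0)
}

#' Planted-clique fixture graphs
#'
#' `c` disjoint cliques of size `s` joined by `bridges` single edges with
#' random endpoints; bridge j joins cliques j and j+1 (round robin), so
#' `bridges = c` yields a ring of cliques.
#'
#' @param c Number of cliques (>= 1).
#' @param s Clique size (>= 2).
#' @param bridges Number of bridge edges (0 for disconnected cliques).
#' @param seed Integer seed for bridge endpoints.
#' @return A list with `graph`, `partition` (clique membership) and
#'   `membership`.
#' @export
generate_planted_cliques <- function(c, s, bridges = 0L, seed = NULL) {
  stopifnot(c >= 1, s >= 2, bridges >= 0)
  c <- as.integer(c); s <- as.integer(s); bridges <- as.integer(bridges)
  if (c < 2 && bridges > 0) stop("bridges need at least two cliques", call. = FALSE)
  edges <- do.call(rbind, lapply(seq_len(c), function(i) {
    off <- (i - 1L) * s
    t(utils::combn(off + seq_len(s), 2L))
  }))
  if (bridges > 0) {
    br <- with_seed(seed, t(vapply(seq_len(bridges), function(j) {
      ci <- (j - 1L) %% c + 1L
      cj <- ci %% c + 1L
      c(sample.int(s, 1L) + (ci - 1L) * s, sample.int(s, 1L) + (cj - 1L) * s)
    }, integer(2))))
    edges <- rbind(edges, br)
  }
  g <- graph_from_edges(edges[, 1L], edges[, 2L])
  memb <- rep(seq_len(c) - 1L, each = s)
  names(memb) <- as.character(seq_len(c * s))
  memb <- memb[igraph::V(g)$name]
  list(graph = g, partition = new_supernode_partition(
         memb[order(as.integer(names(memb)))]),
       membership = memb)
}

#' The 10-node toy network illustrating the super-node sweep
#'
#' A fixed 10-node graph with three planted super nodes, constructed so
#' that (with degree centrality and k = 2): super node {2,3,8,9} is the
#' largest and node 3 its unique degree-maximal member; nodes 1, 4, 5, 6
#' and 10 each have an edge into that super node and are therefore
#' ineligible after node 3 is picked; node 7 has none and is the
#' degree-maximal eligible member of the next super node that yields a
#' spreader, so the selection is (3, 7).  The exact edge list is a frozen
#' construction consistent with all of those facts, not a published one.
#'
#' @return A list with `graph` (10 nodes, 15 edges), `partition` (3 super
#'   nodes) and `membership`.
#' @export
fig1_fixture <- function() {
  el <- rbind(
    c(2L, 3L), c(3L, 8L), c(3L, 9L), c(8L, 9L),   # super node {2,3,8,9}
    c(1L, 3L), c(4L, 2L), c(5L, 8L), c(6L, 9L), c(10L, 2L),  # attachments
    c(1L, 4L), c(4L, 10L), c(1L, 10L),            # super node {1,4,10}
    c(5L, 6L), c(6L, 7L), c(5L, 7L)               # super node {5,6,7}
  )
  g <- graph_from_edges(el[, 1L], el[, 2L])
  memb <- c(`1` = 0L, `4` = 0L, `10` = 0L,
            `2` = 1L, `3` = 1L, `8` = 1L, `9` = 1L,
            `5` = 2L, `6` = 2L, `7` = 2L)
  memb <- memb[order(as.integer(names(memb)))]
  list(graph = g, partition = new_supernode_partition(memb), membership = memb)
}
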