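#' Monte-Carlo information-transfer probability matrix
#'
#' Bond-percolation estimate of the probability that two nodes are
#' connected: in each of N samplings every edge (u,v) is independently
#' "open" with probability \eqn{\beta_{uv} = 1 - (1-\beta)^{w_{uv}}}
#' (\eqn{w_{uv} = 1} on unweighted graphs, so \eqn{\beta_{uv} = \beta});
#' the indicator \eqn{\omega(p,q)} is 1 iff p and q are joined by a path
#' of open edges, and \eqn{m_{pq}} is the mean of \eqn{\omega(p,q)} over
#' the N samplings.
#'
#' @param g An igraph graph (intended for small networks; the matrix is
#'   dense n x n).
#' @param beta Propagation probability in `[0, 1]`.
#' @param N Number of Monte-Carlo samplings.
#' @param seed Optional integer seed.
#' @return A `transfer_matrix`: list with `m` (n x n symmetric matrix,
#'   dimnames = original node ids, unit diagonal), `N`, `beta`.
#' @examples
#' f <- tempfile()
#' writeLines(c("1 2", "2 3"), f)
#' tm <- estimate_transfer_matrix(read_edge_list(f), beta = 1, N = 3)
#' tm$m["1", "3"]  # 1: a path of open edges always exists at beta = 1
#' @export
estimate_transfer_matrix <- function(g, beta, N = 1000L, seed = NULL) {
  if (!is.numeric(beta) || beta < 0 || beta > 1) {
    stop("beta must lie in [0, 1]", call. = FALSE)
  }
  N <- as.integer(N)
  stopifnot(N >= 1L)
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  ne <- nrow(el)
  acc <- matrix(0, n, n)
  with_seed(seed, {
    for (i in seq_len(N)) {
      open <- stats::runif(ne) < beta
      comp <- edge_components(n, el[open, , drop = FALSE])
      acc <- acc + (outer(comp, comp, "==") + 0)
    }
  })
  m <- acc / N
  diag(m) <- 1
  dimnames(m) <- list(igraph::V(g)$name, igraph::V(g)$name)
  structure(list(m = m, N = N, beta = beta), class = "transfer_matrix")
}

# Connected-component labels from an edge subset (union-find, path halving).
edge_components <- function(n, el) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(el)) {
    for (i in seq_len(nrow(el))) {
      ra <- find(el[i, 1L]); rb <- find(el[i, 2L])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("transfer_matrix: %d nodes, beta = %g, N = %d samplings\n",
              nrow(x$m), x$beta, x$N))
  invisible(x)
}

#' Select k spreaders as k-medoids of the transfer-probability distance
#'
#' The k-medoid comparator: nodes are clustered on the distance
#' \eqn{d(p,q) = 1 - m_{pq}} by alternating assignment (each node to its
#' nearest medoid) and update (each cluster's medoid becomes the member
#' minimising the summed within-cluster distance), from a seeded random
#' initial medoid set, until the medoid set is stable or `max_iter` is
#' reached.  The k medoids are returned as the spreaders.
#'
#' Initialisation is farthest-point seeding: the first medoid is a seeded
#' random node and each further medoid maximises its distance to the
#' closest already-chosen medoid (ties to the lowest node id).  A plain
#' random initial set can start all medoids inside one zero-diameter
#' cluster, a configuration the alternating update cannot leave; the
#' spread-out start avoids that degeneracy while staying seeded.
#'
#' @param g An igraph graph.
#' @param tm A `transfer_matrix` from [estimate_transfer_matrix()].
#' @param k Number of spreaders/clusters.
#' @param seed Integer seed for the initial medoid.
#' @param max_iter Iteration cap; non-convergence returns the current
#'   medoids with a warning.
#' @return A `spreader_set` of the k medoid node ids (ascending id order).
#' @export
select_kmedoid <- function(g, tm, k, seed = NULL, max_iter = 100L) {
  n <- igraph::vcount(g)
  k <- check_k(k, n)
  d <- 1 - tm$m
  ids <- as.integer(rownames(d))
  med <- with_seed(seed, sample.int(n, 1L))
  while (length(med) < k) {
    mind <- apply(d[, med, drop = FALSE], 1L, min)
    mind[med] <- -1
    nxt <- which(mind == max(mind))
    med <- c(med, nxt[order(ids[nxt])][1L])
  }
  med <- sort(med)
  for (it in seq_len(max_iter)) {
    # assignment: nearest medoid, ties to the lowest-id medoid
    assign <- max.col(-d[, med, drop = FALSE], ties.method = "first")
    new_med <- vapply(seq_len(k), function(j) {
      cl <- which(assign == j)
      if (!length(cl)) return(med[j])    # empty cluster keeps its medoid
      tot <- colSums(d[cl, cl, drop = FALSE])
      cl[order(tot, ids[cl])][1L]
    }, integer(1))
    new_med <- sort(new_med)
    if (identical(new_med, med)) break
    med <- new_med
    if (it == max_iter) warning("k-medoid did not converge in ", max_iter,
                                " iterations; returning current medoids")
  }
  new_spreader_set(ids[med], "kmedoid", k, NULL)
}
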