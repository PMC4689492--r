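#' Topological summary statistics
#'
#' The descriptive statistics reported for each study network: node and edge
#' counts, average degree \eqn{\langle k\rangle = 2m/n}, mean squared degree
#' \eqn{\langle k^2\rangle}, mean local clustering coefficient, maximal
#' k-core value, and (when a partition is supplied) Newman--Girvan
#' modularity Q.
#'
#' @param g An igraph undirected simple graph.
#' @param partition Optional node-to-community partition (named vector or
#'   `supernode_partition`) for the modularity column.
#' @return A list of class `graph_stats`.
#' @export
graph_stats <- function(g, partition = NULL) {
  out <- list(
    n = igraph::vcount(g),
    m = igraph::ecount(g),
    mean_degree = mean_degree(g),
    mean_sq_degree = mean_squared_degree(g),
    clustering = clustering_coefficient(g),
    max_coreness = max(core_decomposition(g)),
    modularity = if (!is.null(partition)) modularity_q(g, partition) else NA_real_
  )
  structure(out, class = "graph_stats")
}

#' @export
print.graph_stats <- function(x, ...) {
  cat(sprintf("graph: n = %d, m = %d\n", x$n, x$m))
  cat(sprintf("  <k> = %.2f   <k^2> = %.2f   cc = %.3f   max k-core = %d\n",
              x$mean_degree, x$mean_sq_degree, x$clustering, x$max_coreness))
  if (!is.na(x$modularity)) cat(sprintf("  Q = %.3f\n", x$modularity))
  invisible(x)
}

#' Average degree 2m/n
#' @param g An igraph graph; must be non-empty.
#' @return A single real.
#' @export
mean_degree <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("mean degree undefined for empty graph", call. = FALSE)
  2 * igraph::ecount(g) / n
}

#' Mean squared degree
#' @inheritParams mean_degree
#' @export
mean_squared_degree <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("mean squared degree undefined for empty graph", call. = FALSE)
  mean(igraph::degree(g)^2)
}

#' Local clustering coefficient
#'
#' Triangles through a node divided by the number of neighbour pairs;
#' defined as 0 for nodes of degree < 2.  The graph-level coefficient is the
#' unweighted mean over all nodes.
#'
#' @param g An igraph graph.
#' @param u A single original node id, or `NULL` for all nodes.
#' @return A named vector of coefficients (or a single value for one node).
#' @export
local_clustering <- function(g, u = NULL) {
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  if (is.null(u)) return(cc)
  cc[[as.character(as.integer(u))]]
}

#' @rdname local_clustering
#' @export
clustering_coefficient <- function(g) {
  if (igraph::vcount(g) == 0L) return(NA_real_)
  mean(local_clustering(g))
}

#' Coreness of every node
#'
#' Standard k-core peeling: the coreness of a node is the largest k such
#' that it survives iterative removal of all nodes of degree < k.
#'
#' @param g An igraph graph.
#' @return Named integer vector of corenesses (names = original node ids).
#' @export
core_decomposition <- function(g) {
  k <- igraph::coreness(g)
  names(k) <- igraph::V(g)$name
  storage.mode(k) <- "integer"
  k
}

#' Newman--Girvan modularity of a partition
#'
#' \eqn{Q = \sum_c [e_c/m - (d_c/2m)^2]} with \eqn{e_c} the number of
#' intra-community edges and \eqn{d_c} the total degree of community c;
#' resolution fixed at 1, undirected and unweighted.
#'
#' @param g An igraph graph.
#' @param partition Named vector mapping node id to community label, or a
#'   `supernode_partition`.  Must cover every node of `g`.
#' @return Q, a real in \eqn{[-1/2, 1]}.
#' @export
modularity_q <- function(g, partition) {
  if (inherits(partition, "supernode_partition")) partition <- partition$membership
  memb <- partition[igraph::V(g)$name]
  if (anyNA(memb) || anyNA(names(memb))) {
    stop("partition does not cover every node of the graph", call. = FALSE)
  }
  igraph::modularity(g, membership = as.integer(factor(memb)))
}

#' Power-law exponent of the degree distribution (Hill estimator)
#'
#' Maximum-likelihood estimate \eqn{\alpha = 1 + n' / \sum \ln(k_i/(k_{min}-1/2))}
#' over all degrees, with \eqn{k_{min}} the minimum degree present.  This is
#' a fixed-threshold descriptive estimator, not a full distributional fit.
#'
#' @param g An igraph graph with at least 10 nodes, all of degree >= 1
#'   (zero-degree nodes are dropped with a warning).
#' @return The exponent estimate, or `NA` with a warning when all degrees
#'   are equal (the estimator degenerates).
#' @export
power_law_exponent <- function(g) {
  k <- igraph::degree(g)
  if (any(k == 0)) {
    warning("dropping ", sum(k == 0), " zero-degree node(s) from exponent fit")
    k <- k[k > 0]
  }
  if (length(k) < 10L) stop("need at least 10 nodes with degree >= 1", call. = FALSE)
  if (length(unique(k)) == 1L) {
    warning("degenerate (all-equal) degree distribution; exponent undefined")
    return(NA_real_)
  }
  kmin <- min(k)
  1 + length(k) / sum(log(k / (kmin - 0.5)))
}
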