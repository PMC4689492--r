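#' Node influence indices
#'
#' The three centrality indices used to rank candidate spreaders: degree,
#' coreness (k-core), and ClusterRank.  ClusterRank penalises locally
#' clustered nodes: \eqn{s(u) = 10^{-c_u} \sum_{v \in N(u)} (k_v + 1)}
#' with \eqn{c_u} the local clustering coefficient of u; this is the
#' undirected adaptation (degree in place of out-degree).
#'
#' @param g An igraph undirected simple graph.
#' @param index One of `"degree"`, `"kcore"`, `"clusterrank"`.
#' @return A `centrality_scores` object: named numeric vector of scores
#'   (names = original node ids) with an `index` attribute.
#' @examples
#' g <- igraph::make_star(6, mode = "undirected")
#' igraph::V(g)$name <- as.character(1:6)
#' centrality_scores(g, "clusterrank")[["1"]]  # 10
#' @export
centrality_scores <- function(g, index = c("degree", "kcore", "clusterrank")) {
  index <- match.arg(index)
  switch(index,
         degree = degree_centrality(g),
         kcore = kcore_centrality(g),
         clusterrank = clusterrank_centrality(g))
}

new_centrality_scores <- function(scores, index) {
  structure(scores, index = index, class = "centrality_scores")
}

#' @export
print.centrality_scores <- function(x, ...) {
  cat(sprintf("centrality_scores (%s) over %d nodes\n", attr(x, "index"), length(x)))
  print(utils::head(unclass(x), 10L))
  invisible(x)
}

#' @rdname centrality_scores
#' @export
degree_centrality <- function(g) {
  s <- as.numeric(igraph::degree(g))
  names(s) <- igraph::V(g)$name
  new_centrality_scores(s, "degree")
}

#' @rdname centrality_scores
#' @export
kcore_centrality <- function(g) {
  s <- as.numeric(core_decomposition(g))
  names(s) <- igraph::V(g)$name
  new_centrality_scores(s, "kcore")
}

#' @rdname centrality_scores
#' @export
clusterrank_centrality <- function(g) {
  deg <- as.numeric(igraph::degree(g))
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  adjl <- igraph::as_adj_list(g, mode = "all")
  nbsum <- vapply(adjl, function(nb) sum(deg[as.integer(nb)] + 1), numeric(1))
  s <- 10^(-cc) * nbsum
  names(s) <- igraph::V(g)$name
  new_centrality_scores(s, "clusterrank")
}

#' Write centrality scores as two-column ASCII
#' @param scores A `centrality_scores` object.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  writeLines(paste(names(scores), format(unclass(scores), trim = TRUE)), path)
  invisible(path)
}

# Rank node ids by descending score, ties broken by ascending original id.
rank_by_score <- function(scores) {
  ids <- as.integer(names(scores))
  ids[order(-as.numeric(scores), ids)]
}
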