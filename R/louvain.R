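#' One-pass Louvain aggregation into super nodes
#'
#' Runs exactly one iteration of the two-step Louvain (Blondel) procedure
#' on an undirected, unweighted graph.  Phase 1 sweeps the nodes repeatedly
#' in a fixed order, moving each node to the neighbouring community with
#' the largest strictly positive modularity gain, until a full sweep makes
#' no move.  Phase 2 turns each resulting community into one *super node*.
#' No recursive aggregation is performed: the point is to obtain many
#' communities, not the coarsest ones.
#'
#' Phase-1 details: a node is first removed from its community; the gain of
#' joining community c is \eqn{k_{u,c}/m - k_u \, \Sigma_c / (2m^2)} where
#' \eqn{k_{u,c}} counts edges from u into c and \eqn{\Sigma_c} is the total
#' degree of c.  The node moves only if the best neighbouring community
#' beats re-joining its own community by a strictly positive margin; on
#' ties it stays put (standard convention, prevents oscillation).
#'
#' @param g An igraph undirected simple graph, non-empty.
#' @param node_order `"natural"` (ascending original node id, the default,
#'   fully deterministic) or `"random"` (a seeded random permutation).
#' @param seed Integer seed used when `node_order = "random"`.
#' @return A `supernode_partition`: list with `membership` (named integer
#'   vector, node id -> super-node id `0..l-1`), `members` (list of integer
#'   id vectors), `sizes`, and `l`.  Super-node ids are assigned in order
#'   of first appearance when scanning nodes by ascending original id.
#' @examples
#' g <- generate_planted_cliques(2, 3, bridges = 0)$graph
#' louvain_one_pass(g)$l  # 2
#' @export
louvain_one_pass <- function(g, node_order = c("natural", "random"), seed = NULL) {
  node_order <- match.arg(node_order)
  n <- igraph::vcount(g)
  if (n == 0L) stop("cannot partition an empty graph", call. = FALSE)
  m <- igraph::ecount(g)
  ids <- node_ids(g)

  ord <- order(ids)                       # ascending original id
  if (node_order == "random") {
    ord <- with_seed(if (is.null(seed)) NULL else seed, sample(ord))
  }

  comm <- seq_len(n)                      # every node its own community
  if (m > 0L) {
    adjl <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
    deg <- as.numeric(igraph::degree(g))
    tot <- deg                            # total degree per community
    m2sq <- 2 * m^2
    repeat {
      moves <- 0L
      for (u in ord) {
        nb <- adjl[[u]]
        if (!length(nb)) next
        cu <- comm[u]
        tot[cu] <- tot[cu] - deg[u]       # detach u
        nbc <- comm[nb]
        uc <- unique(nbc)
        kuc <- tabulate(match(nbc, uc), nbins = length(uc))
        gain <- kuc / m - deg[u] * tot[uc] / m2sq
        stay <- match(cu, uc)
        base <- if (is.na(stay)) 0 else gain[stay]
        best <- which.max(gain)
        target <- if (gain[best] > base + 1e-12) uc[best] else cu
        if (target != cu) moves <- moves + 1L
        comm[u] <- target
        tot[target] <- tot[target] + deg[u]
      }
      if (moves == 0L) break
    }
  }

  # Phase 2: communities become super nodes, ids 0..l-1 by first appearance
  # in ascending original-node-id order.
  memb <- comm
  names(memb) <- as.character(ids)
  new_supernode_partition(memb[order(ids)])
}

#' Construct a super-node partition from a membership vector
#'
#' @param membership Named vector: names are original node ids, values any
#'   community labels.  Super-node ids are re-coded `0..l-1` in order of
#'   first appearance.
#' @return A `supernode_partition`.
#' @export
new_supernode_partition <- function(membership) {
  if (is.null(names(membership))) stop("membership must be named by node id", call. = FALSE)
  lab <- match(membership, unique(membership)) - 1L
  names(lab) <- names(membership)
  members <- split(as.integer(names(lab)), lab)
  sizes <- lengths(members)
  structure(
    list(membership = lab, members = members,
         sizes = sizes, l = length(members)),
    class = "supernode_partition"
  )
}

#' @export
print.supernode_partition <- function(x, ...) {
  cat(sprintf("supernode_partition: %d super nodes over %d nodes\n",
              x$l, length(x$membership)))
  cat("  sizes: ", paste(utils::head(sort(x$sizes, decreasing = TRUE), 10L),
                         collapse = " "),
      if (x$l > 10L) " ..." else "", "\n", sep = "")
  invisible(x)
}

# Super-node id (0-based) of each of the given original node ids.
supernode_of <- function(p, ids) {
  s <- p$membership[as.character(as.integer(ids))]
  if (anyNA(s)) {
    stop("node id(s) outside partition: ",
         paste(ids[is.na(s)], collapse = ", "), call. = FALSE)
  }
  unname(s)
}
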