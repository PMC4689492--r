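new_spreader_set <- function(nodes, method, k, index = NULL) {
  structure(as.integer(nodes), method = method, k = as.integer(k),
            index = index, class = "spreader_set")
}

#' @export
print.spreader_set <- function(x, ...) {
  cat(sprintf("spreader_set (%s, k = %d): %s\n", attr(x, "method"),
              attr(x, "k"), paste(utils::head(as.integer(x), 20L), collapse = " ")))
  invisible(x)
}

#' Select k spreaders via the super-node sweep
#'
#' The community-aware top-k selection.  Super nodes are visited in
#' decreasing size order (ties by ascending id).  From each visited super
#' node the highest-centrality *eligible* member is taken as a spreader; a
#' node is ineligible once it belongs to, or is adjacent to any member of,
#' a super node that already contains a spreader.  A super node with no
#' eligible member is skipped.  In practice the number of super nodes far
#' exceeds k and the first sweep suffices; if it does not, the visited
#' flags are reset and further sweeps run with the adjacency-exclusion
#' rule dropped (each super node then yields its best not-yet-chosen
#' member) until k spreaders are found.
#'
#' @param g An igraph graph.
#' @param partition A `supernode_partition` of `g` (see
#'   [louvain_one_pass()]).
#' @param scores A `centrality_scores` object on `g`.
#' @param k Number of spreaders, `1 <= k <= n`.
#' @return A `spreader_set`: the k selected original node ids in selection
#'   order, with `method`, `k` and `index` attributes.
#' @examples
#' fx <- fig1_fixture()
#' select_supernode(fx$graph, fx$partition, degree_centrality(fx$graph), 2)
#' @export
select_supernode <- function(g, partition, scores, k) {
  n <- igraph::vcount(g)
  k <- check_k(k, n)
  vids <- node_ids(g)
  sc <- as.numeric(scores)[match(as.character(vids), names(scores))]
  adjl <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  vpos <- function(ids) internal_index(g, ids)

  idx <- build_index(partition)
  blocked <- rep(FALSE, n)   # sweep-1 ineligibility, internal vertex order
  chosen <- rep(FALSE, n)
  picks <- integer(0)
  relaxed <- FALSE

  while (length(picks) < k) {
    sn <- next_unvisited(idx)
    if (is.null(sn)) {
      reset_visits(idx)
      relaxed <- TRUE
      next
    }
    mpos <- vpos(sn$members)
    cand <- if (relaxed) mpos[!chosen[mpos]] else mpos[!blocked[mpos]]
    if (!length(cand)) next
    best <- cand[order(-sc[cand], vids[cand])][1L]
    picks <- c(picks, vids[best])
    chosen[best] <- TRUE
    if (!relaxed) {
      blocked[mpos] <- TRUE
      blocked[unlist(adjl[mpos], use.names = FALSE)] <- TRUE
    }
  }
  new_spreader_set(picks, "supernode", k, attr(scores, "index"))
}

#' Ineligible nodes implied by already-selected spreaders
#'
#' Given the spreaders picked so far, returns the original ids of all
#' nodes excluded from further first-sweep selection: members of any super
#' node containing a spreader, plus every node adjacent to such a member.
#' The spreaders themselves are not listed (they are already taken).
#'
#' @inheritParams select_supernode
#' @param spreaders Integer vector of already-selected node ids.
#' @return Sorted integer vector of ineligible node ids.
#' @export
ineligible_nodes <- function(g, partition, spreaders) {
  sn_ids <- unique(supernode_of(partition, spreaders))
  members <- unlist(partition$members[as.character(sn_ids)], use.names = FALSE)
  mpos <- internal_index(g, members)
  adjl <- igraph::as_adj_list(g, mode = "all")
  nb <- unique(unlist(lapply(adjl[mpos], as.integer), use.names = FALSE))
  out <- union(members, node_ids(g)[nb])
  sort(setdiff(out, as.integer(spreaders)))
}

#' Select the top-k nodes by centrality (influential-node benchmark)
#'
#' @inheritParams select_supernode
#' @return A `spreader_set` with the k highest-scoring node ids (ties by
#'   ascending id), in rank order.
#' @export
select_influential <- function(g, scores, k) {
  k <- check_k(k, igraph::vcount(g))
  new_spreader_set(rank_by_score(scores)[seq_len(k)],
                   "influential", k, attr(scores, "index"))
}

#' Select k unconnected top-ranked nodes (disperse-node benchmark)
#'
#' Walks the centrality ranking in descending order and accepts a node iff
#' it is not adjacent to any already-accepted node, stopping at k.  If the
#' ranking is exhausted first, a shortfall error names the count achieved.
#'
#' @inheritParams select_supernode
#' @return A `spreader_set` of k mutually unconnected node ids.
#' @export
select_disperse <- function(g, scores, k) {
  n <- igraph::vcount(g)
  k <- check_k(k, n)
  vids <- node_ids(g)
  adjl <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  blocked <- rep(FALSE, n)      # adjacent to an accepted node
  picks <- integer(0)
  for (id in rank_by_score(scores)) {
    pos <- match(id, vids)
    if (blocked[pos]) next
    picks <- c(picks, id)
    if (length(picks) == k) break
    blocked[adjl[[pos]]] <- TRUE
  }
  if (length(picks) < k) {
    stop("disperse-node shortfall: only ", length(picks),
         " mutually unconnected spreaders reachable (k = ", k, ")",
         call. = FALSE)
  }
  new_spreader_set(picks, "disperse", k, attr(scores, "index"))
}

check_k <- function(k, n) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n) {
    stop("k must satisfy 1 <= k <= n (n = ", n, ")", call. = FALSE)
  }
  k
}

#' Write a spreader set with a manifest header
#'
#' One node id per line, preceded by `#` comment lines recording the
#' method, centrality index and k.
#'
#' @param s A `spreader_set`.
#' @param path Output path.
#' @param extra Named character vector of extra manifest fields (e.g. seed).
#' @export
write_spreaders <- function(s, path, extra = NULL) {
  hdr <- c(paste("# method:", attr(s, "method")),
           paste("# index:", attr(s, "index") %||% "NA"),
           paste("# k:", attr(s, "k")))
  if (length(extra)) hdr <- c(hdr, paste0("# ", names(extra), ": ", extra))
  writeLines(c(hdr, as.character(as.integer(s))), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
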