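#' Read an undirected simple graph from a whitespace-separated edge list
#'
#' Each non-comment line holds two integer node ids separated by whitespace;
#' lines starting with `#` (and blank lines) are ignored.  Self-loops and
#' duplicate edges are silently collapsed; a message reports how many lines
#' were dropped that way.  Node ids are arbitrary non-negative integers and
#' are preserved as the vertex `name` attribute, so all reported results use
#' the original ids.
#'
#' @param path Path to the edge-list file.
#' @return An [igraph::igraph] undirected simple graph.
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy", "0 1", "1 2"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g)  # 3
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("no edges found in ", path, call. = FALSE)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  lineno <- which(keep)
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    stop("malformed edge list line ", lineno[which(nt < 2L)[1L]],
         " in ", path, ": need two integer node ids", call. = FALSE)
  }
  a <- suppressWarnings(as.integer(vapply(toks, `[`, "", 1L)))
  b <- suppressWarnings(as.integer(vapply(toks, `[`, "", 2L)))
  bad <- which(is.na(a) | is.na(b))
  if (length(bad)) {
    stop("malformed edge list line ", lineno[bad[1L]], " in ", path,
         ": non-integer token", call. = FALSE)
  }
  graph_from_edges(a, b, warn_dropped = TRUE)
}

# Build a simple undirected graph from parallel id vectors, collapsing
# self-loops and duplicate edges.
graph_from_edges <- function(a, b, warn_dropped = FALSE) {
  el <- cbind(as.character(a), as.character(b))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  m0 <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE)
  dropped <- m0 - igraph::ecount(g)
  if (warn_dropped && dropped > 0L) {
    message(dropped, " self-loop/duplicate edge line(s) dropped")
  }
  g
}

#' Write a graph as a two-column edge list
#'
#' One `u v` line per undirected edge, using original node ids.
#'
#' @param g An igraph graph as returned by [read_edge_list()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L]), path)
  invisible(path)
}

#' Write / read a node-to-community partition file
#'
#' Two-column ASCII, `node_id community_id`, one node per line.
#'
#' @param membership Named vector (names = node ids) of community labels,
#'   or a `supernode_partition`.
#' @param path File path.
#' @return `path` (write) or a named integer membership vector (read).
#' @export
write_partition <- function(membership, path) {
  if (inherits(membership, "supernode_partition")) {
    membership <- membership$membership
  }
  writeLines(paste(names(membership), membership), path)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  toks <- strsplit(trimws(readLines(path, warn = FALSE)), "\\s+")
  toks <- toks[lengths(toks) >= 2L]
  memb <- as.integer(vapply(toks, `[`, "", 2L))
  names(memb) <- vapply(toks, `[`, "", 1L)
  memb
}
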