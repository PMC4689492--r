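#' Size-ordered super-node index
#'
#' An ordered index over super nodes supporting logarithmic insertion and
#' search and iteration in strictly decreasing size order (ties broken by
#' ascending super-node id), together with per-entry visited flags.  It is
#' realised as a sorted array with binary search, which meets the same
#' logarithmic search/insert contract as a balanced binary search tree.
#'
#' @param p A `supernode_partition`.
#' @return A `supernode_index` (environment-backed, mutated in place by
#'   [next_unvisited()], [reset_visits()] and [index_insert()]).
#' @examples
#' p <- new_supernode_partition(c(`1` = 0, `2` = 0, `3` = 1))
#' idx <- build_index(p)
#' next_unvisited(idx)$size  # 2
#' @export
build_index <- function(p) {
  ids <- as.integer(names(p$members))
  if (anyDuplicated(ids)) stop("duplicate super-node id", call. = FALSE)
  ord <- order(-p$sizes, ids)
  e <- new.env(parent = emptyenv())
  e$id <- ids[ord]
  e$size <- as.integer(p$sizes[ord])
  e$members <- unname(p$members[ord])
  e$visited <- rep(FALSE, length(ord))
  e$cursor <- 1L
  class(e) <- "supernode_index"
  e
}

#' @export
print.supernode_index <- function(x, ...) {
  cat(sprintf("supernode_index: %d entries, %d visited\n",
              length(x$id), sum(x$visited)))
  invisible(x)
}

#' Number of entries in a super-node index
#' @param idx A `supernode_index`.
#' @export
index_size <- function(idx) length(idx$id)

#' Insert a super node into an ordered index
#'
#' Binary search locates the insertion point under the (size descending,
#' id ascending) order; the new entry starts non-visited.
#'
#' @param idx A `supernode_index`.
#' @param id Integer super-node id (must be new).
#' @param members Integer vector of original node ids.
#' @return `idx`, invisibly.
#' @export
index_insert <- function(idx, id, members) {
  id <- as.integer(id)
  if (id %in% idx$id) stop("duplicate super-node id: ", id, call. = FALSE)
  size <- length(members)
  lo <- 1L; hi <- length(idx$id) + 1L
  while (lo < hi) {                      # first position where entry sorts before
    mid <- (lo + hi) %/% 2L
    before <- idx$size[mid] > size ||
      (idx$size[mid] == size && idx$id[mid] < id)
    if (before) lo <- mid + 1L else hi <- mid
  }
  idx$id <- append(idx$id, id, after = lo - 1L)
  idx$size <- append(idx$size, size, after = lo - 1L)
  idx$members <- append(idx$members, list(as.integer(members)), after = lo - 1L)
  idx$visited <- append(idx$visited, FALSE, after = lo - 1L)
  if (lo < idx$cursor) idx$cursor <- lo
  invisible(idx)
}

#' Take the largest non-visited super node
#'
#' Returns the non-visited super node of maximal size (ties by ascending
#' id) and marks it visited; `NULL` once all entries are visited.
#'
#' @param idx A `supernode_index`.
#' @return A list with `id`, `size`, `members`, or `NULL`.
#' @export
next_unvisited <- function(idx) {
  i <- idx$cursor
  nmax <- length(idx$id)
  while (i <= nmax && idx$visited[i]) i <- i + 1L
  if (i > nmax) {
    idx$cursor <- i
    return(NULL)
  }
  idx$visited[i] <- TRUE
  idx$cursor <- i + 1L
  list(id = idx$id[i], size = idx$size[i], members = idx$members[[i]])
}

#' Clear all visited flags
#'
#' Iteration order is unchanged; the next [next_unvisited()] call returns
#' the overall maximum again.
#'
#' @param idx A `supernode_index`.
#' @return `idx`, invisibly.
#' @export
reset_visits <- function(idx) {
  idx$visited[] <- FALSE
  idx$cursor <- 1L
  invisible(idx)
}
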