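#' @importFrom stats runif rbinom uniroot coef lm
#' @importFrom utils head combn
NULL

# Deterministic sub-seed derivation: one master seed fans out to named
# streams so that changing the replicate count of one stage does not
# perturb the draws of another.  Kept below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 1009 + h * 9973) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`
# (NULL = use the current stream untouched).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Original integer node ids of a graph, in internal vertex order.
node_ids <- function(g) as.integer(igraph::V(g)$name)

# Map original ids to internal vertex indices, erroring on unknown ids.
internal_index <- function(g, ids) {
  idx <- match(as.character(as.integer(ids)), igraph::V(g)$name)
  if (anyNA(idx)) {
    stop("node id(s) not present in graph: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}
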