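#' SIR contact-process parameters
#'
#' The discrete-time SIR contact process is parameterised by the
#' per-contact transmission probability \eqn{\mu}, the per-step recovery
#' probability \eqn{\beta}, and the effective spreading rate
#' \eqn{\lambda = \mu/\beta}.  Supply any two; the third is derived and
#' the constraint \eqn{\mu = \lambda\beta} with \eqn{\mu,\beta \in [0,1]}
#' is enforced.
#'
#' @param lam Effective spreading rate (dimensionless).
#' @param beta Recovery probability per step.
#' @param mu Transmission probability per contact.
#' @param runs Number of independent replicates for [influence_scope()].
#' @param seed Master seed; each replicate runs on a derived sub-seed.
#' @return An `sir_params` list.
#' @export
sir_params <- function(lam = NULL, beta = NULL, mu = NULL,
                       runs = 200L, seed = NULL) {
  if (is.null(mu) && !is.null(lam) && !is.null(beta)) mu <- lam * beta
  if (is.null(lam) && !is.null(mu) && !is.null(beta) && beta > 0) mu / beta -> lam
  if (is.null(beta) && !is.null(mu) && !is.null(lam) && lam > 0) mu / lam -> beta
  if (is.null(mu) || is.null(beta)) {
    stop("supply two of lam, beta, mu", call. = FALSE)
  }
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]", call. = FALSE)
  if (mu < 0 || mu > 1) stop("mu = lam*beta must lie in [0, 1]", call. = FALSE)
  if (!is.null(lam) && abs(mu - lam * beta) > 1e-9) {
    stop("inconsistent parameters: mu must equal lam*beta", call. = FALSE)
  }
  structure(list(lam = lam, beta = beta, mu = mu,
                 runs = as.integer(runs), seed = seed),
            class = "sir_params")
}

#' @export
print.sir_params <- function(x, ...) {
  cat(sprintf("sir_params: lambda = %s, beta = %.4g, mu = %.4g, runs = %d\n",
              if (is.null(x$lam)) "NA" else format(x$lam), x$beta, x$mu, x$runs))
  invisible(x)
}

#' SIR parameters in the standard experimental convention
#'
#' Sets the recovery probability to \eqn{\beta = 1/\langle k\rangle} of
#' the given network and \eqn{\mu = \lambda\beta}, the convention used for
#' all influence-scope experiments (\eqn{\lambda = 1.5} on large networks,
#' 1.1 on the small ones).
#'
#' @param g The network the process will run on.
#' @param lam Effective spreading rate.
#' @inheritParams sir_params
#' @export
auto_sir_params <- function(g, lam = 1.5, runs = 200L, seed = NULL) {
  sir_params(lam = lam, beta = 1 / mean_degree(g), runs = runs, seed = seed)
}

#' One SIR contact-process run
#'
#' All seed nodes start Infected, every other node Susceptible.  In each
#' time step, synchronously against the start-of-step state: every
#' infected node contacts ONE uniformly random neighbour and, if that
#' neighbour is susceptible, infects it with probability \eqn{\mu}
#' (effective from the next step); each infected node then independently
#' recovers with probability \eqn{\beta} — so a node can transmit on the
#' step it recovers.  A contact with a non-susceptible neighbour wastes
#' the step; an isolated infected node only recovers.  The process stops
#' when no infected nodes remain.
#'
#' @param g An igraph graph.
#' @param seeds A `spreader_set` or integer vector of seed node ids.
#' @param params An `sir_params` object.
#' @param seed Optional seed for this single run (overrides `params$seed`).
#' @param trace If `TRUE`, attach a per-step S/I/R count matrix as the
#'   `trace` attribute of the result.
#' @return Final fraction of ever-infected (Recovered) nodes, seeds
#'   included.
#' @export
sir_run <- function(g, seeds, params, seed = NULL, trace = FALSE) {
  n <- igraph::vcount(g)
  spos <- internal_index(g, as.integer(seeds))
  if (!length(spos)) stop("seed set is empty", call. = FALSE)
  adjl <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  with_seed(seed %||% params$seed,
            sir_run_core(adjl, n, spos, params$mu, params$beta, trace))
}

sir_run_core <- function(adjl, n, spos, mu, beta, trace = FALSE) {
  state <- integer(n)                     # 0 = S, 1 = I, 2 = R
  state[spos] <- 1L
  inf <- spos
  hist <- if (trace) list(c(S = n - length(inf), I = length(inf), R = 0L))
  while (length(inf)) {
    ni <- length(inf)
    targets <- vapply(adjl[inf], function(nb) {
      if (length(nb)) nb[sample.int(length(nb), 1L)] else 0L
    }, integer(1))
    hit <- targets[targets > 0L & stats::runif(ni) < mu]
    newinf <- unique(hit[state[hit] == 0L])
    rec <- stats::runif(ni) < beta
    state[inf[rec]] <- 2L
    if (length(newinf)) state[newinf] <- 1L
    inf <- c(inf[!rec], newinf)
    if (trace) hist[[length(hist) + 1L]] <-
        c(S = sum(state == 0L), I = length(inf), R = sum(state == 2L))
  }
  out <- sum(state == 2L) / n
  if (trace) attr(out, "trace") <- do.call(rbind, hist)
  out
}

#' Influence scope: mean final infected fraction over replicates
#'
#' Runs `params$runs` independent [sir_run()] replicates on one RNG
#' stream seeded from `params$seed` and averages the final fractions.
#' Replicates are consumed sequentially from the stream, so increasing
#' `runs` extends the replicate set without perturbing earlier draws.
#'
#' @inheritParams sir_run
#' @return An `sir_outcome`: list with `final_fractions` (one per run) and
#'   `influence_scope` (their mean, the quantity p).
#' @export
influence_scope <- function(g, seeds, params) {
  stopifnot(params$runs >= 1L)
  n <- igraph::vcount(g)
  spos <- internal_index(g, as.integer(seeds))
  adjl <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  fr <- with_seed(params$seed,
                  vapply(seq_len(params$runs), function(i) {
                    sir_run_core(adjl, n, spos, params$mu, params$beta)
                  }, numeric(1)))
  structure(list(final_fractions = fr, influence_scope = mean(fr)),
            class = "sir_outcome")
}

#' @export
print.sir_outcome <- function(x, ...) {
  cat(sprintf("sir_outcome: influence scope p = %.4f over %d runs (sd %.4f)\n",
              x$influence_scope, length(x$final_fractions),
              stats::sd(x$final_fractions)))
  invisible(x)
}

#' Write per-run SIR outcomes
#' @param outcome An `sir_outcome`.
#' @param path Output path.
#' @export
write_outcome <- function(outcome, path) {
  writeLines(c(paste("# influence_scope:", format(outcome$influence_scope)),
               format(outcome$final_fractions, trim = TRUE)), path)
  invisible(path)
}
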