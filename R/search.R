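#' Search configuration
#'
#' All hyperparameters of the partition-space search with their defaults:
#' `n_reactions` N = 4 building blocks; recursion depth `sigma` = 4;
#' at most `gamma` = 150 main-loop iterations; stop once the score exceeds
#' `rho` = 0.8; `lam` = 5 random parameter draws per candidate from the
#' candidate set `Lambda`; input sweep grid `grid` (Omega); `replicates`
#' (theta) = 5 Monte-Carlo initial conditions per grid point; input `E1`,
#' output `P2`; and the relaxation protocol (tau = 10 s, kappa = 360,
#' epsilon = 1e-3).
#'
#' @param n_reactions,sigma,gamma,rho,lam,Lambda,grid,replicates,io,protocol,seed
#'   see description.
#' @return A list of class `ptm_search_config`.
#' @export
search_config <- function(n_reactions = 4L, sigma = 4L, gamma = 150L,
                          rho = 0.8, lam = 5L, Lambda = lambda_candidates(),
                          grid = sweep_grid(), replicates = 5L,
                          io = io_spec(), protocol = solver_protocol(),
                          seed = 1L) {
  stopifnot(sigma >= 0, gamma >= 0, rho > 0, rho <= 1, lam >= 1,
            replicates >= 1)
  structure(list(n_reactions = as.integer(n_reactions),
                 sigma = as.integer(sigma), gamma = as.integer(gamma),
                 rho = rho, lam = as.integer(lam), Lambda = Lambda,
                 grid = grid, replicates = as.integer(replicates), io = io,
                 protocol = protocol, seed = as.integer(seed)),
            class = "ptm_search_config")
}

#' Read / write a search configuration as YAML
#'
#' @param path file path.
#' @return `read_search_config()` returns a `ptm_search_config`.
#' @export
read_search_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("n_reactions", "sigma", "gamma", "rho", "lam", "Lambda",
              "grid", "replicates", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$input) || !is.null(y$output)) {
    args$io <- io_spec(input = y$input %||% "E1", output = y$output %||% "P2")
  }
  if (!is.null(y$protocol)) args$protocol <- do.call(solver_protocol, y$protocol)
  do.call(search_config, args)
}

#' @rdname read_search_config
#' @param config a `ptm_search_config`.
#' @export
write_search_config <- function(config, path) {
  y <- list(n_reactions = config$n_reactions, sigma = config$sigma,
            gamma = config$gamma, rho = config$rho, lam = config$lam,
            Lambda = config$Lambda, grid = config$grid,
            replicates = config$replicates, input = config$io$input,
            output = config$io$output,
            protocol = list(step_time = config$protocol$step_time,
                            max_steps = config$protocol$max_steps,
                            rel_tol = config$protocol$rel_tol),
            seed = config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

# Evaluate through the per-call cache: each distinct canonical partition is
# scored at most once within one psi invocation.
eval_cached <- function(p, evaluator, cache) {
  key <- partition_string(p)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- evaluator(p)
  stopifnot(is.list(res), !is.null(res$score))
  cache[[key]] <- res
  res
}

#' Recursive partition search step
#'
#' The depth-`sigma` recursion over the binary tree of modifier moves:
#' at depth zero return the incumbent `p0`; otherwise generate a join
#' candidate and return it if it beats the incumbent's score, then likewise
#' a separate candidate, then recurse on each candidate at depth
#' `sigma - 1`; if nothing beats the incumbent, return `p0`. The join
#' candidate is always tried first. A modifier no-op (`NULL`) skips that
#' branch. Scores come from `evaluator(p)`, a function returning
#' `list(score = , nu = )`; within one top-level call each distinct
#' partition is evaluated at most once.
#'
#' @param p0 incumbent partition.
#' @param p partition the modifiers act on (initially `p0`).
#' @param sigma remaining recursion depth.
#' @param evaluator scoring function, e.g. a [phi_max()] closure.
#' @param rng a [ptm_rng()] or integer seed.
#' @param io an [io_spec()].
#' @param cache internal evaluation cache (an environment).
#' @return A `ptm_partition`: a candidate scoring strictly above the
#'   incumbent, or `p0`.
#' @export
psi <- function(p0, p, sigma, evaluator, rng, io = io_spec(), cache = NULL) {
  rng <- as_rng(rng)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (sigma <= 0L) return(p0)
  s0 <- eval_cached(p0, evaluator, cache)$score
  p_join <- join_modifier(p, rng, io)
  if (!is.null(p_join) &&
      eval_cached(p_join, evaluator, cache)$score > s0) {
    return(p_join)
  }
  p_sep <- separate_modifier(p, rng, io)
  if (!is.null(p_sep) &&
      eval_cached(p_sep, evaluator, cache)$score > s0) {
    return(p_sep)
  }
  if (!is.null(p_join)) {
    r <- psi(p0, p_join, sigma - 1L, evaluator, rng, io, cache)
    if (eval_cached(r, evaluator, cache)$score > s0) return(r)
  }
  if (!is.null(p_sep)) {
    r <- psi(p0, p_sep, sigma - 1L, evaluator, rng, io, cache)
    if (eval_cached(r, evaluator, cache)$score > s0) return(r)
  }
  p0
}

#' Run the stochastic partition-space search
#'
#' Draws a uniformly random admissible partition and iterates
#' `P <- psi(P, P, sigma)` until the score exceeds `rho` or `gamma`
#' iterations are spent. Each iteration evaluates the incumbent once and
#' explores at most `2^(sigma+1) - 2` candidates.
#'
#' @param config a [search_config()].
#' @param rng a [ptm_rng()] or integer seed; defaults to `config$seed`.
#' @param evaluator optional scoring function `p -> list(score, nu)`;
#'   by default the best-of-`lam` random-parameter bistability score
#'   ([phi_max()]).
#' @param verbose emit a progress line per iteration.
#' @return An object of class `ptm_trace`: a list with `trace` (tibble of
#'   accepted steps: `iteration`, `partition`, `n_blocks`, `score`, and a
#'   list-column `nu`), `final` (partition), `score`, `nu`,
#'   `termination` (`"score"` or `"budget"`) and `evaluations`.
#' @export
run_search <- function(config = search_config(), rng = NULL,
                       evaluator = NULL, verbose = FALSE) {
  rng <- as_rng(if (is.null(rng)) config$seed else rng)
  universe <- build_universe(config$n_reactions)
  n_evals <- 0L
  if (is.null(evaluator)) {
    evaluator <- function(p) {
      res <- phi_max(p, rng, Lambda = config$Lambda, lam = config$lam,
                     grid = config$grid, replicates = config$replicates,
                     io = config$io, protocol = config$protocol)
      list(score = res$score, nu = res$nu)
    }
  }
  counting <- function(p) {
    n_evals <<- n_evals + 1L
    evaluator(p)
  }

  p <- random_partition(universe, rng, io = config$io)
  cache <- new.env(parent = emptyenv())
  cur <- eval_cached(p, counting, cache)
  rows <- list(trace_row(0L, p, cur))
  iter <- 0L
  while (cur$score <= config$rho && iter < config$gamma) {
    iter <- iter + 1L
    cache <- new.env(parent = emptyenv())
    cur <- eval_cached(p, counting, cache)  # fresh incumbent score
    p_new <- psi(p, p, config$sigma, counting, rng, config$io, cache)
    if (!partition_equal(p_new, p)) {
      cur <- eval_cached(p_new, counting, cache)
      p <- p_new
      rows[[length(rows) + 1L]] <- trace_row(iter, p, cur)
    }
    if (verbose) {
      message(sprintf("iter %3d  score %.4f  blocks %d  evals %d",
                      iter, cur$score, n_blocks(p), n_evals))
    }
  }
  structure(list(
    trace = dplyr::bind_rows(rows), final = p, score = cur$score,
    nu = cur$nu,
    termination = if (cur$score > config$rho) "score" else "budget",
    iterations = iter, evaluations = n_evals, config = config
  ), class = "ptm_trace")
}

trace_row <- function(iter, p, res) {
  tibble::tibble(iteration = iter, partition = partition_string(p),
                 n_blocks = n_blocks(p), score = res$score,
                 nu = list(res$nu))
}

#' @export
print.ptm_trace <- function(x, ...) {
  cat("<ptm_trace>", nrow(x$trace), "accepted steps |", x$iterations,
      "iterations |", x$evaluations, "evaluations\n")
  cat("  final score", format(x$score, digits = 4), "|",
      x$termination, "termination\n")
  cat("  final:", partition_string(x$final), "\n")
  invisible(x)
}

#' @rdname tidy.ptm_partition
#' @exportS3Method generics::tidy
#' @export
tidy.ptm_trace <- function(x, ...) x$trace

#' @rdname tidy.ptm_network
#' @exportS3Method generics::glance
#' @export
glance.ptm_trace <- function(x, ...) {
  tibble::tibble(score = x$score, iterations = x$iterations,
                 evaluations = x$evaluations, termination = x$termination,
                 n_blocks = n_blocks(x$final))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
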