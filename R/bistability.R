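#' Default candidate value set and input sweep grid
#'
#' Both the candidate set Lambda (for rate constants and conserved totals)
#' and the input sweep grid Omega are the 21 half-power-of-two values
#' `2^-5, 2^-4.5, ..., 2^5` (mmol/m^3 for concentrations), bracketing the
#' protein concentrations and kinase rate constants reported for the MAPK
#' cascade.
#'
#' @return Numeric vector of length 21, strictly increasing.
#' @export
lambda_candidates <- function() 2^seq(-5, 5, by = 0.5)

#' @rdname lambda_candidates
#' @export
sweep_grid <- function() 2^seq(-5, 5, by = 0.5)

#' Parameter point for a network's dynamics
#'
#' Bundles the rate constants with the conserved totals of every law except
#' the input law, whose total is the swept quantity and therefore not a
#' parameter.
#'
#' @param rates a [rate_constants()].
#' @param totals numeric vector with one entry per conservation law of the
#'   target network, `NA` at the input law's position.
#' @return A list of class `ptm_param`.
#' @export
parameter_point <- function(rates, totals) {
  structure(list(rates = rates, totals = totals), class = "ptm_param")
}

#' Draw a random parameter point from the candidate set
#'
#' Every rate constant (`a_i`, `d_i`, `k_i`) and every non-input conserved
#' total is drawn independently and uniformly from `Lambda`.
#'
#' @param p a `ptm_partition` (or `ptm_network`).
#' @param rng a [ptm_rng()] or integer seed.
#' @param Lambda candidate values, default [lambda_candidates()].
#' @param io an [io_spec()].
#' @return A [parameter_point()].
#' @export
draw_parameter_point <- function(p, rng, Lambda = lambda_candidates(),
                                 io = io_spec()) {
  rng <- as_rng(rng)
  net <- if (inherits(p, "ptm_network")) p else merge_network(p)
  n <- net$n_reactions
  rates <- rate_constants(a = rng_sample(rng, Lambda, n, replace = TRUE),
                          d = rng_sample(rng, Lambda, n, replace = TRUE),
                          k = rng_sample(rng, Lambda, n, replace = TRUE))
  n_laws <- max(net$laws$law)
  totals <- rng_sample(rng, Lambda, n_laws, replace = TRUE)
  totals[input_law_index(net, io)] <- NA_real_
  parameter_point(rates, totals)
}

# law containing the merged species that the io input resolves to
input_law_index <- function(net, io = io_spec()) {
  sp <- unname(net$role_map[io$input])
  unique(net$laws$law[net$laws$species == sp])
}

output_law_index <- function(net, io = io_spec()) {
  sp <- unname(net$role_map[io$output])
  unique(net$laws$law[net$laws$species == sp])
}

#' Monte-Carlo steady-state sweep of the input total
#'
#' For each value of the sweep grid the total concentration of the law
#' containing the input species is fixed at that value, a fresh random
#' initial state is drawn (no state carries over between grid points: this
#' probes coexisting steady states, not a hysteresis continuation), the
#' system is relaxed, and the output species' steady value is recorded
#' normalized to its law's conserved total (a value in `[0, 1]` after
#' clamping round-off). The whole grid pass is repeated `replicates` times;
#' a replicate is valid only if every grid point converged.
#'
#' @param p a `ptm_partition`, admissible for `io`.
#' @param nu a [parameter_point()].
#' @param rng a [ptm_rng()] or integer seed.
#' @param grid sweep grid Omega, default [sweep_grid()].
#' @param replicates number of replicate passes theta (default 5).
#' @param io an [io_spec()].
#' @param protocol a [solver_protocol()].
#' @return An object of class `ptm_sweep`: a list with `tbl` (tibble with
#'   columns `grid_index`, `omega`, `replicate`, `value`, `converged`),
#'   `grid`, `replicate_valid` (logical per replicate), `io`.
#' @export
sweep_input <- function(p, nu, rng, grid = sweep_grid(), replicates = 5L,
                        io = io_spec(), protocol = solver_protocol()) {
  rng <- as_rng(rng)
  if (!is_admissible(p, io)) {
    stop("partition merges input and output species; not admissible",
         call. = FALSE)
  }
  net <- merge_network(p, nu$rates)
  in_law <- input_law_index(net, io)
  out_law <- output_law_index(net, io)
  out_sp <- unname(net$role_map[io$output])
  totals <- nu$totals
  if (length(totals) != max(net$laws$law)) {
    stop("parameter point has ", length(totals), " totals, network has ",
         max(net$laws$law), " conservation laws", call. = FALSE)
  }
  rows <- vector("list", replicates * length(grid))
  ri <- 0L
  for (r in seq_len(replicates)) {
    for (g in seq_along(grid)) {
      tot <- totals
      tot[in_law] <- grid[g]
      init <- random_initial_state(net, tot, rng)
      res <- relax_to_steady_state(net, nu$rates, init, protocol)
      val <- res$state[out_sp] / tot[out_law]
      ri <- ri + 1L
      rows[[ri]] <- tibble::tibble(
        grid_index = g, omega = grid[g], replicate = r,
        value = min(max(unname(val), 0), 1), converged = res$converged
      )
    }
  }
  tbl <- dplyr::bind_rows(rows)
  valid <- vapply(seq_len(replicates), function(r) {
    all(tbl$converged[tbl$replicate == r])
  }, logical(1))
  structure(list(tbl = tbl, grid = grid, replicate_valid = valid, io = io,
                 partition = p, nu = nu),
            class = "ptm_sweep")
}

#' @export
print.ptm_sweep <- function(x, ...) {
  cat("<ptm_sweep>", length(x$grid), "grid points x",
      max(x$tbl$replicate), "replicates;",
      sum(x$replicate_valid), "valid replicates\n")
  invisible(x)
}

#' @rdname tidy.ptm_partition
#' @exportS3Method generics::tidy
#' @export
tidy.ptm_sweep <- function(x, ...) x$tbl

#' Normalized variance vector of a sweep
#'
#' At each grid point, four times the population variance of the valid
#' replicates' normalized outputs. With values in `[0, 1]` the population
#' variance is at most 1/4 (attained when half the values are 0 and half
#' are 1), so each entry lies in `[0, 1]`: 0 means monostable, 1 perfectly
#' bistable.
#'
#' @param result a `ptm_sweep`.
#' @return Numeric vector, one entry per grid point.
#' @export
variance_vector <- function(result) {
  valid <- which(result$replicate_valid)
  if (length(valid) < 2L) {
    stop(structure(
      class = c("ptm_too_few_replicates", "error", "condition"),
      list(message = paste0("only ", length(valid),
                            " valid replicate(s); need at least 2"),
           call = NULL)))
  }
  tbl <- result$tbl[result$tbl$replicate %in% valid, ]
  vapply(seq_along(result$grid), function(g) {
    x <- tbl$value[tbl$grid_index == g]
    4 * mean((x - mean(x))^2)
  }, numeric(1))
}

#' Position-weighted bistability score
#'
#' `wvl(v, l) = (v - |l - 11| / 10)^2` scores one entry of the variance
#' vector: it is maximal for perfect monostability (`v = 0`) at the edges of
#' the 21-point grid and for perfect bistability (`v = 1`) at the centre —
#' the signature of a resettable bistable response.
#'
#' @param v variance value in `[0, 1]`.
#' @param l grid position in `1..21`.
#' @return Numeric score.
#' @export
wvl <- function(v, l) (v - abs(l - 11) / 10)^2

#' Aggregate resettable-bistability score of a variance vector
#'
#' The mean of `wvl(V_l, l)` over the 21 positions, normalized by its
#' maximum 0.6047619 (attained at the ideal vector of six zeros, nine ones,
#' six zeros, where the plain 21-term sum is 12.7) so the ideal vector
#' scores exactly 1.
#'
#' @param V numeric vector of length 21.
#' @return Score in `[0, 1]`.
#' @export
evl <- function(V) {
  if (length(V) != 21L) {
    stop("`V` must have length 21, got ", length(V), call. = FALSE)
  }
  mean(wvl(V, seq_along(V))) / evl_norm_constant()
}

# maximum of the per-position mean of wvl: 12.7 / 21
evl_norm_constant <- function() {
  ideal <- c(rep(0, 6), rep(1, 9), rep(0, 6))
  mean(wvl(ideal, 1:21))
}

#' Resettable-bistability evaluation of a partition at a parameter point
#'
#' Composes [sweep_input()], [variance_vector()] and [evl()]: the score of
#' the network's propensity to be monostable at the edges of the input range
#' and bistable in the middle. If fewer than two replicates converge at
#' every grid point the evaluation fails conservatively with score 0.
#'
#' @inheritParams sweep_input
#' @return Score in `[0, 1]`, with attribute `details` carrying the
#'   variance vector, the sweep and convergence counts.
#' @export
phi <- function(p, nu, rng, grid = sweep_grid(), replicates = 5L,
                io = io_spec(), protocol = solver_protocol()) {
  sw <- sweep_input(p, nu, rng, grid = grid, replicates = replicates,
                    io = io, protocol = protocol)
  V <- tryCatch(variance_vector(sw), ptm_too_few_replicates = function(e) NULL)
  if (is.null(V)) {
    score <- 0
    details <- list(V = NULL, sweep = sw,
                    n_valid = sum(sw$replicate_valid),
                    diagnostic = "fewer than 2 fully converged replicates")
  } else {
    score <- evl(V)
    details <- list(V = V, sweep = sw, n_valid = sum(sw$replicate_valid))
  }
  structure(score, details = details)
}

#' Best-of-lambda random parameter search at a fixed partition
#'
#' Draws `lam` parameter points from the candidate set and returns the
#' highest [phi()] score together with the parameter point that achieved it.
#'
#' @inheritParams sweep_input
#' @param Lambda candidate value set, default [lambda_candidates()].
#' @param lam number of random draws (default 5).
#' @return A list `(score, nu, scores)` where `scores` holds all `lam`
#'   draw scores in order.
#' @export
phi_max <- function(p, rng, Lambda = lambda_candidates(), lam = 5L,
                    grid = sweep_grid(), replicates = 5L, io = io_spec(),
                    protocol = solver_protocol()) {
  stopifnot(lam >= 1, length(Lambda) >= 1)
  rng <- as_rng(rng)
  net <- merge_network(p)
  best <- NULL
  scores <- numeric(lam)
  for (j in seq_len(lam)) {
    nu <- draw_parameter_point(net, rng, Lambda = Lambda, io = io)
    s <- phi(p, nu, rng, grid = grid, replicates = replicates, io = io,
             protocol = protocol)
    scores[j] <- as.numeric(s)
    if (is.null(best) || scores[j] > best$score) {
      best <- list(score = scores[j], nu = nu, details = attr(s, "details"))
    }
  }
  list(score = best$score, nu = best$nu, scores = scores,
       details = best$details)
}
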