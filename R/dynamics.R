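#' Steady-state relaxation protocol
#'
#' The system is integrated in windows of `step_time` seconds (a stiff
#' solver, lsoda) and declared converged when, over one window, every
#' dynamic species changed by less than `rel_tol` relative to the conserved
#' total of the law it belongs to (for complexes belonging to several laws,
#' the smallest such total). At most `max_steps` windows are attempted, so
#' the simulated horizon is `step_time * max_steps` seconds — 3600 s (one
#' hour) at the defaults, the reference response time of a cellular
#' signalling system.
#'
#' @param step_time window length tau in seconds (default 10).
#' @param max_steps maximum number of windows kappa (default 360).
#' @param rel_tol convergence threshold epsilon (default 1e-3).
#' @param atol,rtol integrator absolute/relative tolerances per window.
#' @return A list of class `ptm_protocol`.
#' @export
solver_protocol <- function(step_time = 10, max_steps = 360L, rel_tol = 1e-3,
                            atol = 1e-9, rtol = 1e-6) {
  stopifnot(step_time > 0, max_steps >= 1, rel_tol > 0, rel_tol < 1)
  structure(list(step_time = step_time, max_steps = as.integer(max_steps),
                 rel_tol = rel_tol, atol = atol, rtol = rtol),
            class = "ptm_protocol")
}

#' Random conservation-respecting initial state
#'
#' All complexes start at zero; each conservation law's total is spread over
#' its non-complex members by a flat Dirichlet draw (uniform on the simplex),
#' so every law's multiplicity-weighted sum equals its prescribed total
#' exactly. Because complexes couple the substrate and enzyme laws, putting
#' them at zero is what makes the laws independently satisfiable.
#'
#' @param network a `ptm_network`.
#' @param totals numeric vector of conserved totals, one per law
#'   (mmol/m^3).
#' @param rng a [ptm_rng()] or integer seed.
#' @return Named numeric state vector over `network$species`.
#' @export
random_initial_state <- function(network, totals, rng) {
  rng <- as_rng(rng)
  laws <- network$laws
  n_laws <- max(laws$law)
  stopifnot(length(totals) == n_laws)
  state <- stats::setNames(numeric(length(network$species)), network$species)
  is_complex <- grepl("^C[0-9]+$", laws$species)
  for (l in seq_len(n_laws)) {
    members <- laws$species[laws$law == l & !is_complex]
    w <- rng_rexp(rng, length(members))
    state[members] <- totals[l] * w / sum(w)
  }
  state
}

#' Relax a network to steady state
#'
#' Integrates the mass-action system under the stepwise protocol and reports
#' the final state, whether it converged, and how many windows were used.
#' Tiny negative concentrations from integrator round-off (within ten times
#' the absolute tolerance) are clamped to zero. Integrator failures are
#' caught and reported as non-converged results.
#'
#' @param network a `ptm_network`.
#' @param rates a [rate_constants()].
#' @param state initial state vector over `network$species`.
#' @param protocol a [solver_protocol()].
#' @return A list `(state, converged, steps_used)`.
#' @export
relax_to_steady_state <- function(network, rates = network$rates, state,
                                  protocol = solver_protocol()) {
  f <- compile_rhs(network, rates)
  deriv <- function(t, y, parms) list(f(y))
  # per-species reference totals for the relative convergence test
  tref <- reference_totals(network, state)
  tau <- protocol$step_time
  kappa <- protocol$max_steps
  # integrate in chunks of several windows per solver call: one continuous
  # lsoda run sampled every tau seconds, checked window by window
  chunk <- min(kappa, 36L)
  y <- state
  used <- 0L
  while (used < kappa) {
    n_win <- min(chunk, kappa - used)
    times <- seq(0, n_win * tau, by = tau)
    sol <- tryCatch(
      deSolve::ode(y = y, times = times, func = deriv, parms = NULL,
                   method = "lsoda", atol = protocol$atol,
                   rtol = protocol$rtol),
      error = function(e) e, warning = function(w) w
    )
    if (inherits(sol, "condition") || nrow(sol) < length(times)) {
      msg <- if (inherits(sol, "condition")) conditionMessage(sol) else
        "integration stopped early"
      return(list(state = clamp_state(y, protocol$atol), converged = FALSE,
                  steps_used = used, diagnostic = msg))
    }
    mat <- sol[, -1L, drop = FALSE]
    prev <- y
    for (w in seq_len(n_win)) {
      cur <- mat[w + 1L, ]
      used <- used + 1L
      delta <- abs(cur - prev)
      ok <- ifelse(tref > 0, delta / tref < protocol$rel_tol,
                   delta <= protocol$atol)
      if (all(ok)) {
        return(list(state = clamp_state(cur, protocol$atol), converged = TRUE,
                    steps_used = used))
      }
      prev <- cur
    }
    y <- mat[n_win + 1L, ]
  }
  list(state = clamp_state(y, protocol$atol), converged = FALSE,
       steps_used = used, diagnostic = "window budget exhausted")
}

# Reference scale per species: the conserved total of the law containing it;
# for species in several laws (complexes), the smallest associated total.
reference_totals <- function(network, state) {
  totals <- law_totals(network, state)
  laws <- network$laws
  sp <- network$species
  tref <- stats::setNames(rep(Inf, length(sp)), sp)
  for (r in seq_len(nrow(laws))) {
    s <- laws$species[r]
    tref[s] <- min(tref[s], totals[laws$law[r]])
  }
  tref[!is.finite(tref)] <- 0
  tref
}

clamp_state <- function(y, atol) {
  y[y < 0 & y > -10 * atol] <- 0
  y
}
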