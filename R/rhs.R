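#' Numeric right-hand side of a derived ODE system
#'
#' Evaluates the merged mass-action derivatives at a concentration state.
#' The evaluation agrees exactly with the symbolic monomial table
#' (`tidy(network)`): each monomial contributes
#' `sign * rate * x[f1] * x[f2]`.
#'
#' @param network a `ptm_network`.
#' @param rates a [rate_constants()] (defaults to the rates stored on the
#'   network).
#' @param state named or unnamed numeric vector over `network$species`.
#' @return Numeric derivative vector in species order.
#' @export
rhs <- function(network, rates = network$rates, state) {
  compile_rhs(network, rates)(state)
}

# Build a fast closure state -> derivative. Indices and numeric
# coefficients are resolved once; evaluation is fully vectorized.
compile_rhs <- function(network, rates = network$rates) {
  if (is.null(rates)) stop("no rate constants supplied", call. = FALSE)
  sp <- network$species
  tt <- network$terms
  tgt <- match(tt$species, sp)
  i1 <- match(tt$f1, sp)
  i2 <- match(tt$f2, sp)          # NA for linear terms
  coef <- tt$sign * unname(rates$values[tt$rate])
  if (anyNA(coef)) stop("terms reference unknown rate constants", call. = FALSE)
  lin <- is.na(i2)
  nsp <- length(sp)
  function(state) {
    if (length(state) != nsp) {
      stop("state has length ", length(state), ", expected ", nsp,
           call. = FALSE)
    }
    contrib <- coef * state[i1]
    contrib[!lin] <- contrib[!lin] * state[i2[!lin]]
    d <- numeric(nsp)
    acc <- rowsum(contrib, tgt)
    d[as.integer(rownames(acc))] <- acc[, 1L]
    d
  }
}

#' Multiplicity-weighted conservation-law sums of a state
#'
#' @param network a `ptm_network`.
#' @param state numeric vector over `network$species`.
#' @return Numeric vector, one invariant total per conservation law.
#' @export
law_totals <- function(network, state) {
  sp <- network$species
  laws <- network$laws
  idx <- match(laws$species, sp)
  as.vector(rowsum(laws$multiplicity * state[idx], laws$law)[, 1L])
}
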