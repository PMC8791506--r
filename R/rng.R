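#' Reproducible random-number source
#'
#' A self-contained RNG stream. All stochastic operations in the package
#' (partition modifiers, initial-condition draws, parameter draws, the search)
#' take either a `ptm_rng` object or a plain integer seed; identical seeds
#' give identical sequences, and drawing from a `ptm_rng` never disturbs the
#' global `.Random.seed`.
#'
#' @param seed a single integer.
#' @return An environment of class `ptm_rng` carrying the generator state.
#' @examples
#' r <- ptm_rng(42)
#' @export
ptm_rng <- function(seed) {
  if (inherits(seed, "ptm_rng")) return(seed)
  stopifnot(length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "ptm_rng"
  e
}

#' @export
print.ptm_rng <- function(x, ...) {
  cat("<ptm_rng> private generator stream\n")
  invisible(x)
}

# Evaluate expr with the stream's state installed, then save it back.
with_rng <- function(rng, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

rng_runif <- function(rng, n = 1L) with_rng(rng, stats::runif(n))
rng_rexp <- function(rng, n = 1L) with_rng(rng, stats::rexp(n))

# sample() without the size-1 surprise
rng_sample <- function(rng, x, size = 1L, replace = FALSE) {
  with_rng(rng, x[sample.int(length(x), size, replace = replace)])
}

rng_sample_int <- function(rng, n, size = 1L, replace = FALSE) {
  with_rng(rng, sample.int(n, size, replace = replace))
}

as_rng <- function(rng) {
  if (inherits(rng, "ptm_rng")) rng else ptm_rng(rng)
}
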