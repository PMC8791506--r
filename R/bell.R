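#' Count all enzymatic reaction networks of N reactions
#'
#' Every partition of the 3N-species universe is a distinct network, so the
#' count is the Bell number `B_3N`, computed by the recurrence
#' `B_{n+1} = sum_k choose(n, k) B_k` with `B_0 = B_1 = 1`.
#'
#' @param n_reactions positive integer N.
#' @return `B_{3N}` as a double (exact for `3N <= 21`).
#' @examples
#' count_networks(4) # 4213597 networks of four PTM reactions
#' @export
count_networks <- function(n_reactions) {
  if (length(n_reactions) != 1L || is.na(n_reactions) || n_reactions < 1 ||
      n_reactions != as.integer(n_reactions)) {
    stop("`n_reactions` must be a single positive integer", call. = FALSE)
  }
  bell_numbers(3L * as.integer(n_reactions) + 1L)[3L * n_reactions + 1L]
}

# Bell numbers B_0..B_{len-1} by the binomial recurrence.
bell_numbers <- function(len) {
  b <- numeric(len)
  b[1L] <- 1
  if (len > 1L) {
    for (n in seq_len(len - 1L)) {
      # B_n = sum_{k=0}^{n-1} choose(n-1, k) B_k
      b[n + 1L] <- sum(choose(n - 1L, 0:(n - 1L)) * b[seq_len(n)])
    }
  }
  b
}

# Bell triangle (Aitken's array) — independent cross-check of bell_numbers.
bell_triangle_numbers <- function(len) {
  out <- numeric(len)
  out[1L] <- 1
  row <- 1
  for (n in seq_len(len - 1L)) {
    newrow <- numeric(n + 1L)
    newrow[1L] <- row[n]
    for (j in seq_len(n)) newrow[j + 1L] <- newrow[j] + row[j]
    out[n + 1L] <- newrow[1L]
    row <- newrow
  }
  out
}

#' Enumerate all partitions of a universe
#'
#' Exhaustive enumeration via restricted growth strings, in a deterministic
#' canonical order (species taken in label order; blocks appear ordered by
#' smallest member). Intended for small universes: the count is `B_{3N}`,
#' which reaches 4,213,597 already at `3N = 12`, so the default guard
#' refuses universes above `max_elements` species.
#'
#' @param universe a [build_universe()] object or integer N.
#' @param max_elements refuse enumeration above this many species
#'   (default 12; raise deliberately if you really want millions of objects).
#' @return A list of `ptm_partition` objects of length `count_networks(N)`.
#' @examples
#' length(enumerate_partitions(1)) # 5
#' @export
enumerate_partitions <- function(universe, max_elements = 12L) {
  if (is.numeric(universe)) universe <- build_universe(universe)
  labels <- sort_labels(universe$labels)
  n <- length(labels)
  if (n > max_elements) {
    stop("refusing to enumerate partitions of ", n, " species (> ",
         max_elements, "); raise `max_elements` to override", call. = FALSE)
  }
  out <- vector("list", count_networks(universe$n_reactions))
  pos <- 0L
  a <- integer(n)   # restricted growth string, a[1] = 1
  recurse <- function(i, maxv) {
    if (i > n) {
      pos <<- pos + 1L
      out[[pos]] <<- rgs_to_partition(universe, labels, a)
      return(invisible(NULL))
    }
    for (v in seq_len(maxv + 1L)) {
      a[i] <<- v
      recurse(i + 1L, max(maxv, v))
    }
  }
  a[1L] <- 1L
  recurse(2L, 1L)
  out
}

rgs_to_partition <- function(universe, labels, a) {
  blocks <- split(labels, a)
  ptm_partition(universe, unname(blocks))
}

#' Draw a uniformly random partition
#'
#' Exact uniform sampling over all `B_{3N}` partitions, by the recursive
#' size-of-first-block decomposition `B_n = sum_j choose(n-1, j-1) B_{n-j}`:
#' the block containing the first remaining species has size `j` with
#' probability `choose(n-1, j-1) B_{n-j} / B_n`; its co-members are then a
#' uniform subset, and the remainder is partitioned recursively. Draws are
#' rejected (and redrawn) until admissible for `io`.
#'
#' @param universe a [build_universe()] object or integer N.
#' @param rng a [ptm_rng()] or integer seed.
#' @param io an [io_spec()] used for the admissibility constraint.
#' @param max_tries rejection bound before giving up.
#' @return A `ptm_partition`.
#' @export
random_partition <- function(universe, rng, io = io_spec(), max_tries = 1000L) {
  if (is.numeric(universe)) universe <- build_universe(universe)
  rng <- as_rng(rng)
  bells <- bell_numbers(length(universe$labels) + 1L)
  for (try in seq_len(max_tries)) {
    p <- ptm_partition(universe, sample_blocks(universe$labels, bells, rng))
    if (is_admissible(p, io)) return(p)
  }
  stop("no admissible partition drawn in ", max_tries, " tries", call. = FALSE)
}

sample_blocks <- function(labels, bells, rng) {
  labels <- sort_labels(labels)
  blocks <- list()
  while (length(labels) > 0L) {
    n <- length(labels)
    sizes <- seq_len(n)
    w <- choose(n - 1L, sizes - 1L) * bells[n - sizes + 1L]
    j <- with_rng(rng, sample.int(n, 1L, prob = w))
    co <- if (j > 1L) {
      1L + rng_sample_int(rng, n - 1L, j - 1L)
    } else {
      integer(0)
    }
    pick <- c(1L, co)
    blocks[[length(blocks) + 1L]] <- labels[pick]
    labels <- labels[-pick]
  }
  blocks
}
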