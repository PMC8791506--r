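#' Species universe for N post-translational modification reactions
#'
#' Each PTM reaction `i` contributes a substrate `S<i>`, an enzyme `E<i>` and a
#' product `P<i>`. The universe is the ordered set
#' `{S1, E1, P1, S2, E2, P2, ..., SN, EN, PN}` of these `3N` labels; partitions
#' of this set are the topology representation used throughout the package.
#' Enzyme-substrate complexes `C<i>` never appear in a universe: they exist
#' only in networks derived from a partition.
#'
#' @param n_reactions number of PTM reactions, a positive integer.
#' @return An object of class `ptm_universe`: a list with `n_reactions` and
#'   `labels` (character vector of length `3 * n_reactions`).
#' @examples
#' build_universe(2)
#' @export
build_universe <- function(n_reactions) {
  if (length(n_reactions) != 1L || is.na(n_reactions) ||
      n_reactions < 1 || n_reactions != as.integer(n_reactions)) {
    stop("`n_reactions` must be a single positive integer", call. = FALSE)
  }
  n <- as.integer(n_reactions)
  labels <- as.vector(vapply(seq_len(n), function(i) {
    paste0(c("S", "E", "P"), i)
  }, character(3)))
  structure(list(n_reactions = n, labels = labels), class = "ptm_universe")
}

#' @export
print.ptm_universe <- function(x, ...) {
  cat("<ptm_universe> N =", x$n_reactions, "reactions,",
      length(x$labels), "species\n")
  cat(" ", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

# Parse labels like "S1", "E12" into role and reaction index.
parse_labels <- function(labels) {
  role <- substr(labels, 1L, 1L)
  idx <- suppressWarnings(as.integer(substring(labels, 2L)))
  bad <- !(role %in% c("S", "E", "P", "C")) | is.na(idx) | idx < 1L
  if (any(bad)) {
    stop("malformed species labels: ", paste(labels[bad], collapse = ", "),
         call. = FALSE)
  }
  list(role = role, index = idx)
}

# Total order on species labels: role S < E < P, then reaction index.
# Used for canonical ordering inside blocks and of blocks themselves.
label_rank <- function(labels) {
  p <- parse_labels(labels)
  ord <- c(S = 0L, E = 1L, P = 2L)
  ord[p$role] * 1000000L + p$index
}

sort_labels <- function(labels) labels[order(label_rank(labels))]

same_universe <- function(a, b) {
  a$n_reactions == b$n_reactions
}
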