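#' Partition modifiers: separate and join
#'
#' The two search moves over partition space. `separate_modifier()` picks a
#' block of size >= 2 uniformly at random and splits it into two non-empty
#' parts chosen uniformly among the `2^(m-1) - 1` proper bipartitions of an
#' m-species block. `join_modifier()` merges a uniformly chosen admissible
#' pair of blocks. A pair is inadmissible when it would put the input and
#' output species (see [io_spec()]) into one block; such partitions are
#' excluded from the search space because their bistability score is not
#' defined.
#'
#' When no move is possible (all blocks singletons for separate; a single
#' block, or only the inadmissible pair, for join) the modifiers return
#' `NULL` as a no-op signal that callers must handle.
#'
#' @param p a `ptm_partition`.
#' @param rng a [ptm_rng()] or integer seed.
#' @param io an [io_spec()].
#' @return A new `ptm_partition` with one more (separate) or one fewer
#'   (join) block, or `NULL`.
#' @examples
#' C <- ptm_partition(2, list(c("S1","P2","E2"), c("P1","E1","S2")))
#' separate_modifier(C, ptm_rng(1))
#' @export
separate_modifier <- function(p, rng, io = io_spec()) {
  rng <- as_rng(rng)
  splittable <- which(lengths(p$blocks) >= 2L)
  if (length(splittable) == 0L) return(NULL)
  k <- rng_sample(rng, splittable)
  b <- p$blocks[[k]]
  m <- length(b)
  # Encode a proper bipartition as an integer in 1..2^(m-1)-1: the first
  # species is fixed in part one and the code's bits assign the rest.
  code <- rng_sample_int(rng, 2L^(m - 1L) - 1L)
  bits <- as.integer(intToBits(code))[seq_len(m - 1L)]
  part1 <- b[c(TRUE, bits == 0L)]
  part2 <- b[c(FALSE, bits == 1L)]
  blocks <- c(p$blocks[-k], list(part1, part2))
  ptm_partition(p$universe, blocks)
}

#' @rdname separate_modifier
#' @export
join_modifier <- function(p, rng, io = io_spec()) {
  rng <- as_rng(rng)
  nb <- n_blocks(p)
  if (nb < 2L) return(NULL)
  pairs <- utils::combn(nb, 2L)
  labs <- p$universe$labels
  if (io$input %in% labs && io$output %in% labs) {
    bi <- block_index_of(p, io$input)
    bo <- block_index_of(p, io$output)
    if (bi != bo) {
      keep <- !(pairs[1L, ] == min(bi, bo) & pairs[2L, ] == max(bi, bo))
      pairs <- pairs[, keep, drop = FALSE]
    }
  }
  if (ncol(pairs) == 0L) return(NULL)
  sel <- pairs[, rng_sample_int(rng, ncol(pairs))]
  merged <- c(p$blocks[[sel[1L]]], p$blocks[[sel[2L]]])
  blocks <- c(p$blocks[-sel], list(merged))
  ptm_partition(p$universe, blocks)
}
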