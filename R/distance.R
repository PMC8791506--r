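#' Symmetric-difference size between two blocks
#'
#' `s(a, b) = #(a U b - a n b)`, the number of species in exactly one of the
#' two blocks.
#'
#' @param a,b character vectors of species labels.
#' @return Non-negative integer.
#' @export
block_difference <- function(a, b) {
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Distance between two partitions
#'
#' For partitions `A` and `B` of the same universe, the directional distance
#' of a block `b` to `A` is `d(A, b) = min_a s(a, b)` over blocks `a` of `A`,
#' and `D(A, B) = max(max_b d(A, b), max_a d(B, a))`. `D` is symmetric, zero
#' exactly on equal partitions, and satisfies the triangle inequality, so it
#' metrizes the space of network topologies.
#'
#' @param a,b `ptm_partition` objects over the same universe.
#' @return Non-negative integer distance.
#' @examples
#' A <- ptm_partition(2, list(c("S1","P2","E2"), c("P1","E1"), c("S2")))
#' C <- ptm_partition(2, list(c("S1","P2","E2"), c("P1","E1","S2")))
#' partition_distance(A, C) # 2
#' @export
partition_distance <- function(a, b) {
  if (!same_universe(a$universe, b$universe)) {
    stop("partitions are over different universes", call. = FALSE)
  }
  max(directional_max(a, b), directional_max(b, a))
}

# max over blocks v of `to`, of min over blocks u of `from`, of s(u, v)
directional_max <- function(from, to) {
  max(vapply(to$blocks, function(v) {
    min(vapply(from$blocks, function(u) block_difference(u, v), numeric(1)))
  }, numeric(1)))
}

#' Pairwise distance matrix for a set of partitions
#'
#' @param partitions a list of `ptm_partition` objects over one universe.
#' @param names optional identifiers for rows/columns.
#' @return A symmetric integer matrix with zero diagonal.
#' @export
distance_matrix <- function(partitions, names = NULL) {
  n <- length(partitions)
  if (is.null(names)) names <- paste0("P", seq_len(n))
  m <- matrix(0L, n, n, dimnames = list(names, names))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- partition_distance(partitions[[i]], partitions[[j]])
        m[i, j] <- d
        m[j, i] <- d
      }
    }
  }
  m
}

#' Write a distance matrix as CSV
#'
#' Partition identifiers form the header row and first column.
#'
#' @param m matrix from [distance_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
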