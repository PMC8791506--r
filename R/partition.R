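#' Partitions of a species universe
#'
#' A partition is a family of disjoint, non-empty blocks whose union is the
#' whole universe. Species sharing a block are identified as one chemical
#' species, which is the sole specification of a network's topology: every
#' partition corresponds to exactly one enzymatic reaction network and vice
#' versa.
#'
#' Partitions are stored canonically: within a block, labels are sorted
#' (role order `S < E < P`, then reaction index); blocks are sorted by their
#' smallest label. Two partitions are equal iff their canonical forms are
#' identical.
#'
#' @param universe a [build_universe()] object, or a positive integer N.
#' @param blocks a list of character vectors of species labels
#'   (`"S1"`, `"E2"`, ...). Must cover the universe exactly once.
#' @return An object of class `ptm_partition` with fields `universe` and
#'   `blocks` (canonical).
#' @examples
#' ptm_partition(2, list(c("S1"), c("E1"), c("P1", "E2"), c("S2"), c("P2")))
#' @export
ptm_partition <- function(universe, blocks) {
  if (is.numeric(universe)) universe <- build_universe(universe)
  stopifnot(inherits(universe, "ptm_universe"))
  blocks <- lapply(blocks, function(b) as.character(unlist(b, use.names = FALSE)))
  validate_blocks(universe, blocks)
  structure(list(universe = universe, blocks = canonicalize_blocks(blocks)),
            class = "ptm_partition")
}

validate_blocks <- function(universe, blocks) {
  if (any(lengths(blocks) == 0L)) stop("empty block in partition", call. = FALSE)
  all_members <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    stop("blocks are not disjoint: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(universe$labels, all_members)
  extra <- setdiff(all_members, universe$labels)
  if (length(extra)) {
    stop("labels not in the universe: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (length(missing)) {
    stop("labels missing from the partition: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

canonicalize_blocks <- function(blocks) {
  blocks <- lapply(blocks, sort_labels)
  blocks[order(vapply(blocks, function(b) label_rank(b[1L]), numeric(1)))]
}

#' @export
print.ptm_partition <- function(x, ...) {
  cat("<ptm_partition> N =", x$universe$n_reactions, "|",
      n_blocks(x), "blocks\n ", partition_string(x), "\n")
  invisible(x)
}

#' @export
format.ptm_partition <- function(x, ...) partition_string(x)

#' Number of blocks of a partition
#' @param p a `ptm_partition`.
#' @return integer block count.
#' @export
n_blocks <- function(p) length(p$blocks)

# Canonical one-line serialization; doubles as hash key for caches.
partition_string <- function(p) {
  paste0("{", paste(vapply(p$blocks, function(b) {
    paste0("{", paste(b, collapse = ","), "}")
  }, character(1)), collapse = ", "), "}")
}

#' Test two partitions for equality
#'
#' Equality is canonical-form identity over the same universe.
#' @param a,b `ptm_partition` objects.
#' @return logical.
#' @export
partition_equal <- function(a, b) {
  same_universe(a$universe, b$universe) &&
    identical(partition_string(a), partition_string(b))
}

# The block (as label vector) containing a given label, or NA.
block_of <- function(p, label) {
  for (b in p$blocks) if (label %in% b) return(b)
  NULL
}

# Index of the block containing a label.
block_index_of <- function(p, label) {
  for (k in seq_along(p$blocks)) if (label %in% p$blocks[[k]]) return(k)
  NA_integer_
}

#' Is a partition admissible for a given input/output choice?
#'
#' The search space excludes partitions that merge the input species and the
#' output species into one block: the bistability score normalizes the output
#' by its conserved total while the input's total is being swept, so such
#' partitions have no well-defined score. If either label is absent from the
#' universe (e.g. `P2` when N = 1) the constraint is vacuous.
#'
#' @param p a `ptm_partition`.
#' @param io an [io_spec()]; default input `E1`, output `P2`.
#' @return logical.
#' @export
is_admissible <- function(p, io = io_spec()) {
  labs <- p$universe$labels
  if (!(io$input %in% labs) || !(io$output %in% labs)) return(TRUE)
  block_index_of(p, io$input) != block_index_of(p, io$output)
}

#' Input/output species specification
#'
#' Declares which species is the swept input and which is the scored output.
#' The defaults follow the convention that input and output belong to
#' different PTM reactions.
#'
#' @param input,output species labels.
#' @return A list of class `ptm_io`.
#' @export
io_spec <- function(input = "E1", output = "P2") {
  stopifnot(is.character(input), is.character(output), input != output)
  parse_labels(c(input, output))
  structure(list(input = input, output = output), class = "ptm_io")
}

#' Read / write a partition as JSON
#'
#' The on-disk form is `{"n_reactions": N, "blocks": [["S1","P2"], ...]}`.
#' The reader validates coverage and disjointness; the writer emits canonical
#' order, so read/write round-trips are identity on canonical partitions.
#'
#' @param path file path.
#' @return `read_partition_json()` returns a `ptm_partition`;
#'   `write_partition_json()` returns `path` invisibly.
#' @export
read_partition_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$n_reactions) || is.null(obj$blocks)) {
    stop("partition JSON must have fields `n_reactions` and `blocks`",
         call. = FALSE)
  }
  ptm_partition(as.integer(obj$n_reactions),
                lapply(obj$blocks, function(b) as.character(unlist(b))))
}

#' @rdname read_partition_json
#' @param p a `ptm_partition`.
#' @export
write_partition_json <- function(p, path) {
  obj <- list(n_reactions = p$universe$n_reactions, blocks = p$blocks)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Tidy a partition into a long tibble
#'
#' @param x a `ptm_partition`.
#' @param ... unused.
#' @return A tibble with one row per species: `block` (integer id in
#'   canonical order), `label`, `role`, `reaction`.
#' @exportS3Method generics::tidy
#' @export
tidy.ptm_partition <- function(x, ...) {
  labels <- unlist(x$blocks, use.names = FALSE)
  p <- parse_labels(labels)
  tibble::tibble(
    block = rep.int(seq_along(x$blocks), lengths(x$blocks)),
    label = labels, role = p$role, reaction = p$index
  )
}
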