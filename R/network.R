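#' Rate constants for N PTM reactions
#'
#' Each Michaelis-Menten-type reaction `S_i + E_i <=> C_i -> P_i + E_i` has an
#' association constant `a_i` (m^3/mmol/s), a dissociation constant `d_i`
#' (1/s) and a catalytic constant `k_i` (1/s). All must be strictly positive.
#'
#' @param a,d,k numeric vectors of equal length N.
#' @return An object of class `ptm_rates`.
#' @examples
#' rate_constants(a = c(1, 2), d = c(0.5, 0.5), k = c(1, 1))
#' @export
rate_constants <- function(a, d, k) {
  stopifnot(length(a) == length(d), length(d) == length(k))
  if (any(!is.finite(c(a, d, k))) || any(c(a, d, k) <= 0)) {
    stop("rate constants must be strictly positive and finite", call. = FALSE)
  }
  n <- length(a)
  v <- c(a, d, k)
  names(v) <- c(paste0("a", seq_len(n)), paste0("d", seq_len(n)),
                paste0("k", seq_len(n)))
  structure(list(n_reactions = n, values = v), class = "ptm_rates")
}

#' @export
print.ptm_rates <- function(x, ...) {
  cat("<ptm_rates> N =", x$n_reactions, "\n")
  print(x$values)
  invisible(x)
}

#' Mass-action rate equations of the unmerged reactions
#'
#' For each reaction `i` the law of mass action gives four equations:
#' \deqn{\dot S_i = -a_i S_i E_i + d_i C_i}
#' \deqn{\dot E_i = -a_i S_i E_i + (d_i + k_i) C_i}
#' \deqn{\dot C_i = +a_i S_i E_i - (d_i + k_i) C_i}
#' \deqn{\dot P_i = k_i C_i}
#' Terms are stored as signed monomials: one row per monomial with its rate
#' constant symbol and one or two concentration factors. `(d_i + k_i) C_i`
#' is two rows.
#'
#' @param n_reactions positive integer N.
#' @return A tibble with columns `species`, `sign`, `rate`, `f1`, `f2`.
#' @export
base_equations <- function(n_reactions) {
  stopifnot(n_reactions >= 1)
  rows <- lapply(seq_len(as.integer(n_reactions)), function(i) {
    S <- paste0("S", i); E <- paste0("E", i)
    C <- paste0("C", i); P <- paste0("P", i)
    a <- paste0("a", i); d <- paste0("d", i); k <- paste0("k", i)
    tibble::tibble(
      species = c(S, S, E, E, E, C, C, C, P),
      sign    = c(-1L, 1L, -1L, 1L, 1L, 1L, -1L, -1L, 1L),
      rate    = c(a, d, a, d, k, a, d, k, k),
      f1      = c(S, C, S, C, C, S, C, C, C),
      f2      = c(E, NA, E, NA, NA, E, NA, NA, NA)
    )
  })
  dplyr::bind_rows(rows)
}

# Display name of a merged species: the single label for singleton blocks,
# else the bracketed canonical member list, e.g. "[S2,E1,E4,P1]".
merged_name <- function(block) {
  if (length(block) == 1L) block else paste0("[", paste(block, collapse = ","), "]")
}

#' Derive the reaction network of a partition
#'
#' Builds the merged mass-action ODE system: each block becomes one dynamic
#' species whose rate law is the sum of its members' unmerged rate laws, with
#' every occurrence of a member species (in any equation, including the
#' block's own) replaced by the merged species. Blocks whose substrate and
#' enzyme coincide produce squared-concentration terms mechanically (dimer
#' formation). The `N` enzyme-substrate complexes `C_i` remain individual
#' dynamic species, so a network with `m` blocks has `m + N` dynamic species.
#'
#' @param p a `ptm_partition`.
#' @param rates optional [rate_constants()] stored on the network for
#'   numeric evaluation.
#' @return An object of class `ptm_network` with fields `partition`,
#'   `species` (dynamic species names, merged blocks then complexes),
#'   `role_map` (raw label -> dynamic species), `terms` (monomial tibble as
#'   in [base_equations()]), `laws` (conservation-law tibble from
#'   [conservation_laws()]) and `rates`.
#' @examples
#' p <- ptm_partition(2, list("S1", "E1", c("P1", "E2"), "S2", "P2"))
#' merge_network(p)
#' @export
merge_network <- function(p, rates = NULL) {
  stopifnot(inherits(p, "ptm_partition"))
  n <- p$universe$n_reactions
  if (!is.null(rates) && rates$n_reactions != n) {
    stop("rate constants are for ", rates$n_reactions,
         " reactions, network has ", n, call. = FALSE)
  }
  base <- base_equations(n)

  block_names <- vapply(p$blocks, merged_name, character(1))
  complexes <- paste0("C", seq_len(n))
  # raw label -> dynamic species
  role_map <- c(
    stats::setNames(rep(block_names, lengths(p$blocks)),
                    unlist(p$blocks, use.names = FALSE)),
    stats::setNames(complexes, complexes)
  )

  terms <- base
  terms$species <- unname(role_map[terms$species])
  terms$f1 <- unname(role_map[terms$f1])
  terms$f2 <- ifelse(is.na(terms$f2), NA_character_, unname(role_map[terms$f2]))
  # canonical factor order within a monomial
  swap <- !is.na(terms$f2) & terms$f2 < terms$f1
  tmp <- terms$f1[swap]
  terms$f1[swap] <- terms$f2[swap]
  terms$f2[swap] <- tmp

  species <- c(block_names, complexes)
  terms$species <- factor(terms$species, levels = species)
  terms <- terms[order(terms$species), , drop = FALSE]
  terms$species <- as.character(terms$species)

  net <- structure(
    list(partition = p, n_reactions = n, species = species,
         role_map = role_map, terms = tibble::as_tibble(terms),
         laws = NULL, rates = rates),
    class = "ptm_network"
  )
  net$laws <- conservation_laws(p, net)
  net
}

#' Conservation laws of a partition's network
#'
#' Starts from the `2N` per-reaction laws `{S_i, C_i, P_i}` (substrate) and
#' `{E_i, C_i}` (enzyme) and processes each block in turn: every list sharing
#' a species with the block is concatenated (concatenated, not unioned — the
#' repeats are the point, because distinct lists can share a complex), the
#' block's members are removed, and the merged species is added. A species'
#' multiplicity in a law is the number of times it appears in the
#' concatenation; the multiplicity-weighted sum of each law is invariant
#' under the dynamics.
#'
#' @param p a `ptm_partition`.
#' @param net optional pre-built `ptm_network` (internal use).
#' @return A tibble with columns `law` (integer id), `species`,
#'   `multiplicity`. Every merged species appears in exactly one law;
#'   complexes may appear in several and/or with multiplicity > 1.
#' @export
conservation_laws <- function(p, net = NULL) {
  n <- p$universe$n_reactions
  q <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    q[[2L * i - 1L]] <- c(paste0("S", i), paste0("C", i), paste0("P", i))
    q[[2L * i]] <- c(paste0("E", i), paste0("C", i))
  }
  for (b in p$blocks) {
    hits <- which(vapply(q, function(l) any(b %in% l), logical(1)))
    r <- unlist(q[hits], use.names = FALSE)
    r <- r[!(r %in% b)]
    r <- c(r, merged_name(b))
    q <- c(q[-hits], list(r))
  }
  species_order <- c(vapply(p$blocks, merged_name, character(1)),
                     paste0("C", seq_len(n)))
  # stable law order: by earliest member in the network's species order
  lead <- vapply(q, function(l) min(match(l, species_order)), numeric(1))
  q <- q[order(lead)]
  rows <- lapply(seq_along(q), function(k) {
    tab <- table(q[[k]])
    tibble::tibble(law = k, species = names(tab),
                   multiplicity = as.integer(tab))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$law, match(out$species, species_order)), , drop = FALSE]
  tibble::as_tibble(out)
}

# Collapse monomials: group by (species, rate, f1, f2), sum signs into an
# integer coefficient, drop zero rows. Canonical form for symbolic equality
# and for polynomial-identity checks.
canonical_terms <- function(terms) {
  key <- paste(terms$species, terms$rate, terms$f1,
               ifelse(is.na(terms$f2), "", terms$f2), sep = "\r")
  agg <- rowsum(terms$sign, key)
  keep <- agg[, 1L] != 0
  parts <- strsplit(rownames(agg)[keep], "\r", fixed = TRUE)
  out <- tibble::tibble(
    species = vapply(parts, `[`, character(1), 1L),
    coef = as.integer(agg[keep, 1L]),
    rate = vapply(parts, `[`, character(1), 2L),
    f1 = vapply(parts, `[`, character(1), 3L),
    f2 = vapply(parts, function(x) if (length(x) >= 4L && nzchar(x[4L])) x[4L] else NA_character_, character(1))
  )
  out[order(out$species, out$rate, out$f1, out$f2, method = "radix"), ]
}

#' @export
print.ptm_network <- function(x, ...) {
  cat("<ptm_network> N =", x$n_reactions, "|", length(x$species),
      "dynamic species |", max(x$laws$law), "conservation laws\n")
  cat("  partition:", partition_string(x$partition), "\n")
  for (sp in x$species) {
    tt <- x$terms[x$terms$species == sp, ]
    rhs <- paste(vapply(seq_len(nrow(tt)), function(r) {
      f <- paste0("x[", tt$f1[r], "]")
      if (!is.na(tt$f2[r])) f <- paste0(f, " x[", tt$f2[r], "]")
      paste0(if (tt$sign[r] > 0) "+ " else "- ", tt$rate[r], " ", f)
    }, character(1)), collapse = " ")
    cat("  dx[", sp, "]/dt = ", rhs, "\n", sep = "")
  }
  invisible(x)
}

#' Tidy and glance methods for derived networks
#'
#' `tidy()` returns the signed monomial table of the ODE right-hand sides;
#' `glance()` a one-row summary.
#'
#' @param x a `ptm_network`.
#' @param ... unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.ptm_network <- function(x, ...) x$terms

#' @rdname tidy.ptm_network
#' @exportS3Method generics::glance
#' @export
glance.ptm_network <- function(x, ...) {
  tibble::tibble(
    n_reactions = x$n_reactions,
    n_blocks = n_blocks(x$partition),
    n_species = length(x$species),
    n_terms = nrow(x$terms),
    n_laws = max(x$laws$law)
  )
}
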