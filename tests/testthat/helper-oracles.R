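# Independent oracles used across the suite. These deliberately avoid the
# package's own enumeration/derivation code paths.

# Brute-force set partitions of a small label vector: all block-label
# assignments, deduplicated as sets of sets.
brute_partitions <- function(labels) {
  n <- length(labels)
  grids <- do.call(expand.grid, rep(list(seq_len(n)), n))
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (r in seq_len(nrow(grids))) {
    blocks <- unname(split(labels, as.integer(grids[r, ])))
    key <- paste(sort(vapply(blocks, function(b) paste(sort(b), collapse = ","),
                             character(1))), collapse = "|")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <- blocks
    }
  }
  out
}

# Numeric evaluator for a monomial table (independent of compile_rhs):
# plain loop over rows.
eval_terms <- function(terms, rate_values, state) {
  d <- stats::setNames(numeric(length(unique(terms$species))),
                       unique(terms$species))
  for (r in seq_len(nrow(terms))) {
    v <- terms$sign[r] * rate_values[[terms$rate[r]]] * state[[terms$f1[r]]]
    if (!is.na(terms$f2[r])) v <- v * state[[terms$f2[r]]]
    d[terms$species[r]] <- d[terms$species[r]] + v
  }
  d
}

# Polynomial check that the multiplicity-weighted sum of the rate terms over
# each conservation law cancels identically: collect monomials by
# (rate, f1, f2) and require all coefficient sums to vanish.
law_polynomials_vanish <- function(net) {
  laws <- net$laws
  for (l in unique(laws$law)) {
    members <- laws[laws$law == l, ]
    keys <- character(0)
    coefs <- numeric(0)
    for (r in seq_len(nrow(members))) {
      tt <- net$terms[net$terms$species == members$species[r], ]
      if (nrow(tt) == 0L) next
      k <- paste(tt$rate, tt$f1, ifelse(is.na(tt$f2), "", tt$f2))
      keys <- c(keys, k)
      coefs <- c(coefs, members$multiplicity[r] * tt$sign)
    }
    sums <- rowsum(coefs, keys)
    if (any(sums != 0)) return(FALSE)
  }
  TRUE
}

# Canonical monomial table as a plain sorted data.frame for exact equality;
# the factor pair of a bilinear term is order-normalized first.
canon_df <- function(terms) {
  swap <- !is.na(terms$f2) & terms$f2 < terms$f1
  tmp <- terms$f1[swap]
  terms$f1[swap] <- terms$f2[swap]
  terms$f2[swap] <- tmp
  df <- as.data.frame(ptmnet:::canonical_terms(terms))
  rownames(df) <- NULL
  df
}

random_test_partition <- function(n, rng) {
  random_partition(build_universe(n), rng)
}

# A partition one join away from the initial partition that run_search will
# draw from `seed`: merge the first admissible block pair.
planted_join_neighbor <- function(seed, n = 2) {
  rng <- ptm_rng(seed)
  u <- build_universe(n)
  p0 <- random_partition(u, rng)
  stopifnot(n_blocks(p0) >= 3)
  bi <- ptmnet:::block_index_of(p0, "E1")
  bo <- ptmnet:::block_index_of(p0, "P2")
  pair <- c(1L, 2L)
  if (bi %in% pair && bo %in% pair) pair <- c(1L, 3L)
  ptm_partition(u, c(p0$blocks[-pair],
                     list(c(p0$blocks[[pair[1]]], p0$blocks[[pair[2]]]))))
}
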