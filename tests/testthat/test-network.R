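test_that("unmerged rate equations follow the law of mass action", {
  eq <- base_equations(2)
  # substrate equation of reaction 2: -a2 S2 E2 + d2 C2
  s2 <- eq[eq$species == "S2", ]
  expect_equal(s2$sign, c(-1L, 1L))
  expect_equal(s2$rate, c("a2", "d2"))
  # product equation: single catalytic term k2 C2
  p2 <- eq[eq$species == "P2", ]
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$rate, "k2")
  expect_equal(p2$f1, "C2")
  # per reaction, S + C + P and E + C cancel as polynomials
  for (i in 1:2) {
    sub <- eq[eq$species %in% paste0(c("S", "C", "P"), i), ]
    expect_equal(sum(abs(rowsum(sub$sign, paste(sub$rate, sub$f1, sub$f2)))), 0)
    enz <- eq[eq$species %in% paste0(c("E", "C"), i), ]
    expect_equal(sum(abs(rowsum(enz$sign, paste(enz$rate, enz$f1, enz$f2)))), 0)
  }
})

test_that("merging P1 with E2 reproduces the activation-chain system", {
  p <- ptm_partition(2, list("S1", "E1", c("P1", "E2"), "S2", "P2"))
  net <- merge_network(p)
  expect_length(net$species, n_blocks(p) + 2)
  y <- "[E2,P1]"
  expected <- tibble::tibble(
    species = c("S1", "S1",
                "E1", "E1", "E1",
                "C1", "C1", "C1",
                y, y, y, y,
                "S2", "S2",
                "C2", "C2", "C2",
                "P2"),
    sign = c(-1L, 1L,  -1L, 1L, 1L,  1L, -1L, -1L,
             1L, -1L, 1L, 1L,  -1L, 1L,  1L, -1L, -1L,  1L),
    rate = c("a1", "d1",  "a1", "d1", "k1",  "a1", "d1", "k1",
             "k1", "a2", "d2", "k2",  "a2", "d2",  "a2", "d2", "k2",  "k2"),
    f1   = c("S1", "C1",  "S1", "C1", "C1",  "S1", "C1", "C1",
             "C1", y, "C2", "C2",  y, "C2",  y, "C2", "C2",  "C2"),
    f2   = c("E1", NA,  "E1", NA, NA,  "E1", NA, NA,
             NA, "S2", NA, NA,  "S2", NA,  "S2", NA, NA,  NA)
  )
  expect_equal(canon_df(net$terms), canon_df(expected))
})

test_that("the discrete partition is an identity merge", {
  u <- build_universe(2)
  p <- ptm_partition(u, as.list(u$labels))
  net <- merge_network(p)
  expect_equal(canon_df(net$terms), canon_df(base_equations(2)))
  # 2N per-reaction laws survive untouched
  laws <- split(net$laws$species, net$laws$law)
  sigs <- sort(vapply(laws, function(s) paste(sort(s), collapse = ","),
                      character(1)))
  expect_equal(unname(sigs), sort(c("C1,P1,S1", "C1,E1", "C2,P2,S2", "C2,E2")))
  expect_true(all(net$laws$multiplicity == 1))
})

test_that("self-referential merges produce autocatalytic and dimer terms", {
  # autocatalysis: E1 = P1
  net_e <- merge_network(ptm_partition(1, list("S1", c("E1", "P1"))))
  y <- "[E1,P1]"
  expected_y <- tibble::tibble(
    species = c(y, y, y, y),
    sign = c(-1L, 1L, 1L, 1L),
    rate = c("a1", "d1", "k1", "k1"),
    f1 = c("S1", "C1", "C1", "C1"),
    f2 = c(y, NA, NA, NA)
  )
  got <- net_e$terms[net_e$terms$species == y, ]
  expect_equal(canon_df(got), canon_df(expected_y))

  # dimer formation-separation: S1 = E1 = P1, squared mass-action term
  net_g <- merge_network(ptm_partition(1, list(c("S1", "E1", "P1"))))
  z <- "[S1,E1,P1]"
  gz <- canon_df(net_g$terms[net_g$terms$species == z, ])
  sq <- gz[gz$rate == "a1", ]
  expect_equal(sq$coef, -2L)
  expect_equal(sq$f1, z)
  expect_equal(sq$f2, z)
  expect_equal(gz$coef[gz$rate == "d1"], 2L)
  expect_equal(gz$coef[gz$rate == "k1"], 2L)
})

test_that("conservation laws reproduce the worked example with multiplicity", {
  # activation chain: printed list of three laws
  net <- merge_network(ptm_partition(2, list("S1", "E1", c("P1", "E2"),
                                             "S2", "P2")))
  laws <- split(net$laws$species, net$laws$law)
  sigs <- sort(vapply(laws, function(s) paste(sort(s), collapse = ","),
                      character(1)))
  expect_equal(unname(sigs),
               sort(c("C1,C2,S1,[E2,P1]", "C1,E1", "C2,P2,S2")))
  expect_true(all(net$laws$multiplicity == 1))

  # S1 = E1: the complex enters the merged law twice (y + 2 C1 + P1)
  laws2 <- conservation_laws(ptm_partition(1, list(c("S1", "E1"), "P1")))
  expect_equal(max(laws2$law), 1)
  expect_equal(laws2$multiplicity[laws2$species == "C1"], 2L)
  expect_equal(sort(laws2$species), sort(c("[S1,E1]", "C1", "P1")))
})

test_that("conservation is a polynomial identity on random partitions", {
  rng <- ptm_rng(777)
  for (i in 1:60) {
    n <- ((i - 1) %% 3) + 1
    net <- merge_network(random_test_partition(n, rng))
    expect_true(law_polynomials_vanish(net))
    expect_lte(max(net$laws$law), 2 * n)
    # each merged species sits in exactly one law
    merged <- setdiff(net$species, paste0("C", seq_len(n)))
    for (m in merged) expect_equal(sum(net$laws$species == m), 1L)
  }
})

test_that("conservation derivation is invariant under block order", {
  p <- ptm_partition(3, list(c("S1", "E2"), c("P1", "S2", "E3"),
                             c("P2", "S3"), "E1", c("P3")))
  sig <- function(laws) {
    sort(vapply(split(paste0(laws$multiplicity, "*", laws$species), laws$law),
                function(s) paste(sort(s), collapse = "+"), character(1)),
         method = "radix")
  }
  base_sig <- sig(conservation_laws(p))
  set.seed(31)
  for (i in 1:10) {
    q <- p
    q$blocks <- q$blocks[sample(length(q$blocks))]  # bypass canonicalization
    expect_equal(unname(sig(conservation_laws(q))), unname(base_sig))
  }
})

test_that("numeric rhs matches the symbolic terms and conserves the laws", {
  rates <- rate_constants(a = c(1, 2), d = c(0.5, 0.25), k = c(3, 0.75))
  p <- ptm_partition(2, list("S1", "E1", c("P1", "E2"), "S2", "P2"))
  net <- merge_network(p, rates)

  # all-zero state: mass action vanishes at the origin
  expect_equal(rhs(net, rates, numeric(length(net$species))),
               numeric(length(net$species)))

  rng <- ptm_rng(99)
  for (i in 1:20) {
    st <- stats::setNames(ptmnet:::rng_runif(rng, length(net$species)) + 0.05,
                          net$species)
    d <- rhs(net, rates, st)
    # independent slow evaluator over the monomial table
    oracle <- eval_terms(net$terms, as.list(rates$values), as.list(st))
    expect_equal(d, unname(oracle[net$species]), tolerance = 1e-12)
    # law derivatives vanish to machine precision
    laws <- net$laws
    for (l in unique(laws$law)) {
      m <- laws[laws$law == l, ]
      expect_equal(sum(m$multiplicity * d[match(m$species, net$species)]),
                   0, tolerance = 1e-12)
    }
  }

  # hand-computed single-reaction value: S=E=1, C=P=0, a=d=k=1
  r1 <- rate_constants(1, 1, 1)
  net1 <- merge_network(ptm_partition(1, list("S1", "E1", "P1")), r1)
  d1 <- rhs(net1, r1, c(S1 = 1, E1 = 1, P1 = 0, C1 = 0)[net1$species])
  expect_equal(d1[match("S1", net1$species)], -1)
  expect_equal(d1[match("C1", net1$species)], 1)
  expect_error(rhs(net1, r1, c(1, 2)), "length")
})

test_that("merged rates equal summed unmerged rates at consistent states", {
  # state where P1 and E2 share the value of their merged species
  p <- ptm_partition(2, list("S1", "E1", c("P1", "E2"), "S2", "P2"))
  rates <- rate_constants(a = c(1.5, 0.5), d = c(1, 2), k = c(0.25, 4))
  net <- merge_network(p, rates)
  base <- base_equations(2)
  st_base <- list(S1 = 0.3, E1 = 0.8, P1 = 0.6, S2 = 0.9, E2 = 0.6,
                  P2 = 0.1, C1 = 0.2, C2 = 0.4)
  f <- eval_terms(base, as.list(rates$values), st_base)
  st_merged <- stats::setNames(
    c(0.3, 0.8, 0.6, 0.9, 0.1, 0.2, 0.4),
    c("S1", "E1", "[E2,P1]", "S2", "P2", "C1", "C2"))[net$species]
  d <- rhs(net, rates, st_merged)
  expect_equal(d[match("[E2,P1]", net$species)],
               unname(f[["P1"]] + f[["E2"]]), tolerance = 1e-12)
  expect_equal(d[match("S2", net$species)], unname(f[["S2"]]),
               tolerance = 1e-12)
})

test_that("tidy and glance summarize networks", {
  net <- merge_network(load_fixture("fig2a"))
  expect_s3_class(tidy(net), "tbl_df")
  g <- glance(net)
  expect_equal(g$n_species, 8)
  expect_equal(g$n_blocks, 4)
  expect_equal(g$n_laws, 2)
})
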