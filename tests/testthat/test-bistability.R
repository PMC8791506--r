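ideal_V <- c(rep(0, 6), rep(1, 9), rep(0, 6))

test_that("wvl scores monostable edges and bistable centre maximally", {
  expect_equal(wvl(1, 11), 1)
  expect_equal(wvl(0, 1), 1)
  expect_equal(wvl(0, 21), 1)
  expect_equal(wvl(0.5, 11), 0.25)
  expect_equal(wvl(1, 1), 0)
})

test_that("evl normalization reproduces the stated maximum", {
  # plain 21-term sum at the ideal vector is 12.7; per-position mean 0.604762
  expect_equal(sum(wvl(ideal_V, 1:21)), 12.7, tolerance = 1e-12)
  expect_equal(round(mean(wvl(ideal_V, 1:21)), 6), 0.604762)
  expect_equal(evl(ideal_V), 1, tolerance = 1e-12)
  # frozen by direct evaluation: mean((|l-11|/10)^2) = 7.7/21
  expect_equal(evl(rep(0, 21)), (7.7 / 21) / (12.7 / 21), tolerance = 1e-12)
  expect_error(evl(rep(0, 20)), "length 21")
})

test_that("evl attains its maximum value at the ideal vector", {
  # per-coordinate maximization of wvl over v in {0,1} (wvl is convex in v,
  # so the max over [0,1] is at an endpoint); ties at |l-11| = 5 share the
  # ideal value
  per_max <- vapply(1:21, function(l) max(wvl(0, l), wvl(1, l)), numeric(1))
  expect_equal(mean(per_max) / (12.7 / 21), evl(ideal_V), tolerance = 1e-12)
  # random vectors never beat it
  set.seed(1)
  for (i in 1:200) {
    expect_lte(evl(stats::runif(21)), 1 + 1e-12)
  }
})

test_that("fourfold population variance measures bistability", {
  pv <- function(x) mean((x - mean(x))^2)
  expect_equal(4 * pv(c(0, 0, 1, 1)), 1)
  expect_equal(4 * pv(c(0.3, 0.3, 0.3)), 0)
  expect_equal(4 * pv(c(0, 0, 1, 1, 1)), 0.96)
  # population variance of values in [0,1] is at most 1/4
  set.seed(2)
  for (i in 1:200) expect_lte(pv(stats::runif(5)), 0.25)
})

test_that("sweeps record normalized outputs per replicate and grid point", {
  p <- load_fixture("fig1a")
  net <- merge_network(p)
  rates <- rate_constants(c(1, 1), c(1, 1), c(1, 1))
  totals <- rep(NA_real_, max(net$laws$law))
  totals[-ptmnet:::input_law_index(net)] <- 1
  nu <- parameter_point(rates, totals)
  grid <- 2^seq(-2, 2, by = 1)
  sw <- sweep_input(p, nu, ptm_rng(5), grid = grid, replicates = 3)
  expect_s3_class(sw, "ptm_sweep")
  expect_equal(nrow(sw$tbl), length(grid) * 3)
  expect_true(all(sw$tbl$value >= 0 & sw$tbl$value <= 1))
  expect_true(all(sw$tbl$converged))
  expect_equal(sum(sw$replicate_valid), 3)
  # determinism under the seed
  sw2 <- sweep_input(p, nu, ptm_rng(5), grid = grid, replicates = 3)
  expect_identical(sw$tbl, sw2$tbl)
  # inadmissible partition is refused
  bad <- ptm_partition(2, list(c("E1", "P2"), "S1", "P1", "S2", "E2"))
  expect_error(sweep_input(bad, nu, ptm_rng(1)), "admissible")
})

test_that("a frozen output keeps its initial allocation", {
  # discrete network with zero total for the E2 enzyme law: C2 never forms,
  # so P2 keeps whatever the initial draw allocated
  u <- build_universe(2)
  p <- ptm_partition(u, as.list(u$labels))
  net <- merge_network(p, rate_constants(c(1, 1), c(1, 1), c(1, 1)))
  totals <- c(1, 0.5, 2, 0)  # laws: {S1,C1,P1}, {E1,C1}, {S2,C2,P2}, {E2,C2}
  st <- random_initial_state(net, totals, ptm_rng(77))
  res <- relax_to_steady_state(net, net$rates, st)
  expect_true(res$converged)
  expect_equal(unname(res$state[["P2"]]), unname(st[["P2"]]),
               tolerance = 1e-6)
})

test_that("variance_vector requires two fully converged replicates", {
  p <- load_fixture("fig1a")
  net <- merge_network(p)
  totals <- rep(NA_real_, max(net$laws$law))
  totals[-ptmnet:::input_law_index(net)] <- 1
  nu <- parameter_point(rate_constants(c(1, 1), c(1, 1), c(1, 1)), totals)
  sw <- sweep_input(p, nu, ptm_rng(3), grid = c(0.5, 1, 2), replicates = 2)
  sw$replicate_valid <- c(TRUE, FALSE)
  expect_error(variance_vector(sw), class = "ptm_too_few_replicates")
})

test_that("phi of a monostable chain equals the all-zero baseline", {
  p <- load_fixture("fig1a")  # feed-forward chain, unique steady state
  net <- merge_network(p)
  totals <- rep(NA_real_, max(net$laws$law))
  totals[-ptmnet:::input_law_index(net)] <- 1
  nu <- parameter_point(rate_constants(c(1, 1), c(1, 1), c(1, 1)), totals)
  s <- phi(p, nu, ptm_rng(12), replicates = 3)
  expect_gte(as.numeric(s), 0)
  expect_lte(as.numeric(s), 1)
  expect_equal(as.numeric(s), evl(rep(0, 21)), tolerance = 1e-3)
  d <- attr(s, "details")
  expect_equal(d$n_valid, 3)
  expect_lt(max(d$V), 1e-3)
})

test_that("phi_max returns the argmax over its parameter draws", {
  p <- load_fixture("fig1a")
  res1 <- phi_max(p, ptm_rng(6), lam = 1, replicates = 2)
  expect_length(res1$scores, 1)
  expect_equal(res1$score, res1$scores[1])
  res3 <- phi_max(p, ptm_rng(6), lam = 3, replicates = 2)
  expect_equal(res3$score, max(res3$scores))
  expect_equal(res3$scores[1], res1$scores[1])  # same stream prefix
  # determinism
  res3b <- phi_max(p, ptm_rng(6), lam = 3, replicates = 2)
  expect_equal(res3$scores, res3b$scores)
  expect_equal(res3$nu$rates$values, res3b$nu$rates$values)
})
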