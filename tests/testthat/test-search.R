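# Deterministic stub evaluators make the search machinery testable without
# any ODE work.
constant_evaluator <- function(value = 0.5) {
  function(p) list(score = value, nu = NULL)
}

planted_evaluator <- function(target) {
  function(p) list(score = if (partition_equal(p, target)) 1 else 0.1,
                   nu = NULL)
}

counting_wrapper <- function(evaluator, counter) {
  function(p) {
    counter$n <- counter$n + 1L
    evaluator(p)
  }
}


test_that("psi at depth zero returns the incumbent without evaluating", {
  p0 <- ptm_partition(1, list("S1", "E1", "P1"))
  counter <- new.env(); counter$n <- 0L
  res <- psi(p0, p0, 0, counting_wrapper(constant_evaluator(), counter),
             ptm_rng(1))
  expect_true(partition_equal(res, p0))
  expect_equal(counter$n, 0L)
})

test_that("psi returns a planted one-join-away optimum", {
  p0 <- ptm_partition(1, list("S1", "E1", "P1"))
  target <- ptm_partition(1, list("S1", c("E1", "P1")))
  # N = 1 has three blocks and three join pairs; the depth-2 recursion
  # redraws pairs until the planted one comes up (seeded draw)
  res <- psi(p0, p0, 2, planted_evaluator(target), ptm_rng(4))
  expect_true(partition_equal(res, target))
  # and the planted partition is indeed one join away: some join of p0
  # equals it
  joins <- unique(vapply(1:50, function(i) {
    format(join_modifier(p0, ptm_rng(i)))
  }, character(1)))
  expect_true(format(target) %in% joins)
})

test_that("psi explores at most 2^(sigma+1) - 2 candidates", {
  # binary recursion tree: each of the 2^sigma - 1 expanding calls
  # generates at most one join and one separate candidate
  p0 <- random_partition(build_universe(2), ptm_rng(13))
  for (sigma in c(1, 2, 3, 4)) {
    counter <- new.env(); counter$n <- 0L
    seen <- new.env(); seen$keys <- character(0)
    ev <- function(p) {
      counter$n <- counter$n + 1L
      seen$keys <- c(seen$keys, format(p))
      list(score = 0.5, nu = NULL)
    }
    res <- psi(p0, p0, sigma, ev, ptm_rng(100 + sigma))
    expect_true(partition_equal(res, p0))   # nothing beats a constant score
    candidates <- setdiff(unique(seen$keys), format(p0))
    expect_lte(length(candidates), 2^(sigma + 1) - 2)
    # caching: each distinct partition evaluated at most once
    expect_equal(counter$n, length(unique(seen$keys)))
  }
})

test_that("run_search stops immediately when the first score clears rho", {
  cfg <- search_config(n_reactions = 2, sigma = 2, gamma = 10, seed = 3)
  tr <- run_search(cfg, evaluator = constant_evaluator(1.0))
  expect_equal(tr$termination, "score")
  expect_equal(tr$iterations, 0L)
  expect_equal(nrow(tr$trace), 1L)
  expect_equal(tr$evaluations, 1L)
})

test_that("run_search exhausts the budget under a constant evaluator", {
  cfg <- search_config(n_reactions = 2, sigma = 4, gamma = 150, seed = 5)
  tr <- run_search(cfg, evaluator = constant_evaluator(0.2))
  expect_equal(tr$termination, "budget")
  expect_equal(tr$iterations, 150L)
  expect_equal(nrow(tr$trace), 1L)     # no candidate ever accepted
  # per iteration: one incumbent + at most 2^(sigma+1) - 2 candidates
  expect_lte(tr$evaluations, 1 + 150 * (2^5 - 2 + 1))
})

test_that("run_search with gamma = 0 records only the initial partition", {
  cfg <- search_config(n_reactions = 2, sigma = 2, gamma = 0, seed = 11)
  tr <- run_search(cfg, evaluator = constant_evaluator(0.3))
  expect_equal(nrow(tr$trace), 1L)
  expect_equal(tr$trace$iteration, 0L)
  expect_equal(tr$score, 0.3)
})

test_that("run_search finds a planted optimum and is seed-deterministic", {
  # plant the optimum one join away from the seed's own initial partition
  target <- planted_join_neighbor(2)
  cfg <- search_config(n_reactions = 2, sigma = 3, gamma = 50, seed = 2)
  tr <- run_search(cfg, evaluator = planted_evaluator(target))
  expect_equal(tr$termination, "score")
  expect_true(partition_equal(tr$final, target))
  expect_equal(tr$score, 1)
  # accepted scores never decrease
  expect_true(all(diff(tr$trace$score) >= 0))
  tr2 <- run_search(cfg, evaluator = planted_evaluator(target))
  expect_identical(tr$trace$partition, tr2$trace$partition)
  expect_identical(tr$trace$score, tr2$trace$score)
})

test_that("search configs round-trip through YAML", {
  cfg <- search_config(n_reactions = 3, sigma = 2, gamma = 30, rho = 0.7,
                       lam = 4, replicates = 3, seed = 17)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_search_config(cfg, path)
  back <- read_search_config(path)
  for (f in c("n_reactions", "sigma", "gamma", "rho", "lam", "replicates",
              "seed")) {
    expect_equal(back[[f]], cfg[[f]], info = f)
  }
  expect_equal(back$Lambda, cfg$Lambda)
  expect_equal(back$io$input, "E1")
})
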