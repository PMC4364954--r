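test_that("null choice simulation is fair-coin per decision", {
  withr::local_seed(1)
  sims <- simulate_null_choices(rep(4L, 8), n_reps = 10000)
  # per-dyad mean count ~ Binomial(4, .5): mean 2, se = 1/sqrt(10000)
  means <- rowMeans(sims)
  se <- sqrt(4 * 0.25 / 10000)
  expect_true(all(abs(means - 2) < 3 * se))
  expect_true(all(sims >= 0 & sims <= 4))

  one <- simulate_null_choices(1L, n_reps = 2000)
  expect_setequal(unique(as.vector(one)), c(0L, 1L))

  expect_error(simulate_null_choices(integer(0)), "at least one")
  expect_error(simulate_null_choices(c(4L, 0L)), ">= 1")
})

test_that("Monte Carlo p-values follow the at-least-as-far-away rule", {
  draws <- c(0.1, 0.2, 0.5)
  # observed distance zero: every draw qualifies
  expect_equal(mc_p_value(0.5, draws, reference = 0.5), 1)
  expect_equal(mc_p_value(0.5, draws, reference = 0.5,
                          convention = "plus_one"), 1)
  # observed beyond every draw
  ten <- seq(0.1, 1, by = 0.1)
  expect_equal(mc_p_value(2, ten, reference = 0), 0)
  expect_equal(mc_p_value(2, ten, reference = 0, convention = "plus_one"),
               1 / 11)
  # non-strict: draws exactly at the observed distance count
  expect_equal(mc_p_value(0.5, c(0.5, 0.4), reference = 0), 0.5)
  # two-sided distance: reflection through the reference leaves p unchanged
  sym <- c(0.3, 0.7, 0.45, 0.55, 0.5)
  expect_equal(mc_p_value(0.8, sym, reference = 0.5),
               mc_p_value(0.2, sym, reference = 0.5))
})

test_that("strategy tests are bitwise reproducible from the seed", {
  ds <- simulate_dataset(null_config(11))
  cfg <- analysis_config(seed = 5, n_reps = 400)
  a <- pure_strategy_test(ds, cfg)
  b <- pure_strategy_test(ds, cfg)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$null_summary, b$null_summary)
  c1 <- common_strategy_test(ds, cfg)
  c2 <- common_strategy_test(ds, cfg)
  expect_identical(c1$p_value, c2$p_value)
  # a different seed moves the null draws
  d <- pure_strategy_test(ds, analysis_config(seed = 6, n_reps = 400))
  expect_false(identical(a$null_summary, d$null_summary))
})

test_that("degenerate and extreme datasets give the forced p-values", {
  # every dyad fully deterministic: observed statistic at its maximum
  mono <- make_dataset(
    lapply(1:12, function(i) {
      make_dyad_trials(paste0("m", i), c("A", "A", "A", "A"))
    })
  )
  cfg <- analysis_config(seed = 3, n_reps = 2000)
  pure <- pure_strategy_test(mono, cfg)
  expect_equal(pure$observed_statistic, 0.5)
  # a qualifying rep needs all 12 dyads at 0/4 or 4/4: prob (1/8)^12
  expect_lt(pure$p_value, 0.001)

  # a single dyad with one successful trial: every rep is also at 0.5
  solo <- make_dataset(make_dyad_trials("s", c("A", "N", "N", "N")))
  expect_equal(pure_strategy_test(solo, cfg)$p_value, 1)

  # observed common statistic exactly at chance
  half <- make_dataset(
    make_dyad_trials("h1", c("A", "A", "E", "E")),
    make_dyad_trials("h2", c("E", "E", "B", "A"))
  )
  expect_equal(common_strategy_test(half, cfg)$observed_statistic, 0.5)
  expect_equal(common_strategy_test(half, cfg)$p_value, 1)

  # no eligible dyads
  void <- make_dataset(make_dyad_trials("v", c("N", "N", "N", "N")))
  expect_error(pure_strategy_test(void, cfg), "undefined")
})

test_that("successless dyads are excluded and counted", {
  ds <- make_dataset(
    make_dyad_trials("a", c("A", "A", "A", "A")),
    make_dyad_trials("b", c("E", "E", "E", "E")),
    make_dyad_trials("void", c("N", "N", "N", "N"))
  )
  res <- pure_strategy_test(ds, analysis_config(seed = 1, n_reps = 100))
  expect_equal(res$n_dyads_included, 2L)
  expect_equal(res$n_dyads_excluded, 1L)
})

test_that("p is non-increasing in the observed distance for fixed draws", {
  withr::local_seed(9)
  draws <- rbinom(1000, 12, 0.5) / 12
  obs <- seq(0.5, 1, by = 0.05)
  ps <- vapply(obs, mc_p_value, numeric(1),
               null_draws = draws, reference = 0.5)
  expect_true(all(diff(ps) <= 0))
})

test_that("attained type-I error matches the exact discrete level, and the tests are valid", {
  # Exact rejection probability of each test at alpha = .05 for 12 dyads
  # of 4 fair-coin decisions, from an independent convolution oracle.
  pmf_pure <- c(6, 8, 2) / 16 # |k - 2| for k ~ Bin(4, .5)
  exact_pure <- oracle_discrete_rejection(pmf_pure, 12, 0.05)
  pmf_common_folded <- local({
    # |sum - 24| built from the unfolded sum of 12 Bin(4,.5)
    d <- 1
    for (i in 1:12) {
      nd <- numeric(length(d) + 4)
      for (j in 0:4) {
        idx <- seq_along(d) + j
        nd[idx] <- nd[idx] + d * dbinom(j, 4, 0.5)
      }
      d <- nd
    }
    dev <- abs(0:48 - 24)
    vapply(0:24, function(c0) sum(d[dev == c0]), numeric(1))
  })
  exact_common <- oracle_discrete_rejection(pmf_common_folded, 1, 0.05)

  set.seed(77)
  n_repl <- 200
  rej <- matrix(FALSE, n_repl, 2)
  for (r in seq_len(n_repl)) {
    ds <- simulate_dataset(null_config(seed = sample.int(1e8, 1)))
    cfg <- analysis_config(seed = sample.int(1e8, 1), n_reps = 1000)
    rej[r, 1] <- pure_strategy_test(ds, cfg)$p_value <= 0.05
    rej[r, 2] <- common_strategy_test(ds, cfg)$p_value <= 0.05
  }
  rates <- colMeans(rej)
  for (j in 1:2) {
    exact <- c(exact_pure, exact_common)[j]
    se <- sqrt(exact * (1 - exact) / n_repl)
    # within 3 SE of the exact attainable level (plus a little slack for
    # the 1000-rep noise in each p-value), and never anti-conservative
    expect_lt(abs(rates[j] - exact), 3 * se + 0.015)
    expect_lte(rates[j], 0.05 + 2 * sqrt(0.05 * 0.95 / n_repl))
  }
})

test_that("pure and common tests dissociate opposite-direction determinism", {
  # half the dyads always unequal, half always equal: strong pure
  # strategies with no common direction
  split <- make_dataset(
    lapply(1:6, function(i) {
      make_dyad_trials(paste0("u", i), c("A", "B", "A", "A"))
    }),
    lapply(1:6, function(i) {
      make_dyad_trials(paste0("e", i), c("E", "E", "E", "E"))
    })
  )
  cfg <- analysis_config(seed = 8, n_reps = 2000)
  expect_lte(pure_strategy_test(split, cfg)$p_value, 0.01)
  expect_gte(common_strategy_test(split, cfg)$p_value, 0.5)
})
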