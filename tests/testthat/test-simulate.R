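test_that("simulation is bitwise reproducible from its seed", {
  cfg <- simulation_config(
    design_exp1(),
    groups = study_groups(strategy_spec(
      "random",
      p_no_agreement = 0.1, p_coordination_failure = 0.1,
      protest_against_small = 0.5, p_change_of_tray = 0.3
    )),
    seed = 123
  )
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$trials, b$trials)
  cfg2 <- cfg
  cfg2$seed <- 124L
  expect_false(identical(simulate_dataset(cfg2)$trials, a$trials))
})

test_that("generated datasets always satisfy the core invariants", {
  for (seed in 1:30) {
    spec <- strategy_spec(
      "random",
      p_unequal = runif(1), p_dominant_large = runif(1),
      p_no_agreement = runif(1, 0, 0.4),
      p_coordination_failure = runif(1, 0, 0.4),
      protest_against_small = runif(1), protest_against_equal = runif(1),
      p_change_of_tray = runif(1)
    )
    cfg <- simulation_config(design_exp2(),
                             groups = study_groups(spec, experiment = 2L,
                                                   n_per_age = 3),
                             seed = seed)
    # dyad_dataset() re-validates every invariant on construction
    expect_s3_class(simulate_dataset(cfg), "dyad_dataset")
  }
})

test_that("study-shaped layout balances covariates", {
  groups <- study_groups(strategy_spec("random"))
  tab <- dplyr::bind_rows(lapply(groups, function(g) {
    tibble::tibble(age_group = g$age_group, gender = g$gender,
                   familiarity = g$familiarity, n = g$n_dyads)
  }))
  expect_equal(sum(tab$n), 24)
  by_age <- tapply(tab$n, tab$age_group, sum)
  expect_true(all(by_age == 12))
  expect_true(all(tab$n == 3)) # 3 dyads per gender x familiarity cell
})

test_that("deterministic strategies force their outcome patterns", {
  mono <- simulate_dataset(simulation_config(
    design_exp1(), groups = study_groups(strategy_spec("monopolist")),
    seed = 2
  ))
  sm <- summarize_dyads(mono)
  expect_true(all(sm$n_unequal == 4))
  expect_true(all(sm$big_count_a == 4)) # dominant child is A
  expect_true(all(sm$prop_diff == 0.5))

  eq <- simulate_dataset(simulation_config(
    design_exp1(), groups = study_groups(strategy_spec("equal_preferrer")),
    seed = 2
  ))
  expect_true(all(summarize_dyads(eq)$n_equal == 4))

  alt <- simulate_dataset(simulation_config(
    design_exp1(), groups = study_groups(strategy_spec("alternator")),
    seed = 2
  ))
  sma <- summarize_dyads(alt)
  expect_true(all(sma$big_count_a == 2 & sma$big_count_b == 2))
})

test_that("alternation skips failed trials without advancing the turn", {
  # with coordination failures, successful unequal trials still alternate
  cfg <- simulation_config(
    design_exp1(),
    groups = study_groups(
      strategy_spec("alternator", p_coordination_failure = 0.4),
      n_per_age = 6
    ),
    seed = 31
  )
  ds <- simulate_dataset(cfg)
  for (id in unique(ds$trials$dyad_id)) {
    seq_large <- ds$trials$large_recipient[
      ds$trials$dyad_id == id & ds$trials$large_recipient != "none"
    ]
    if (length(seq_large) > 1) {
      expect_true(all(seq_large[-1] != seq_large[-length(seq_large)]))
    }
    if (length(seq_large) > 0) expect_equal(seq_large[1], "A")
  }
})

test_that("empirical frequencies converge to the specified probabilities", {
  spec <- strategy_spec("random", p_unequal = 0.3, p_no_agreement = 0.2,
                        p_coordination_failure = 0.25,
                        protest_against_small = 0.6,
                        p_change_of_tray = 0.15)
  cfg <- simulation_config(
    tray_design(2, 3, 1, n_test_trials = 10L),
    groups = list(list(experiment = 1L, age_group = "5", gender = "M",
                       familiarity = "unfamiliar", n_dyads = 1000L,
                       strategy = spec)),
    seed = 99
  )
  tr <- simulate_dataset(cfg)$trials # 10,000 trials
  n <- nrow(tr)
  tol <- function(p, m) 3 * sqrt(p * (1 - p) / m)
  p_na <- mean(tr$outcome == "no_agreement")
  expect_lt(abs(p_na - 0.2), tol(0.2, n))
  agreed <- tr[tr$outcome != "no_agreement", ]
  expect_lt(abs(mean(agreed$tray == "unequal") - 0.3),
            tol(0.3, nrow(agreed)))
  expect_lt(abs(mean(agreed$outcome == "unsuccessful_agreement") - 0.25),
            tol(0.25, nrow(agreed)))
  uneq <- agreed[agreed$tray == "unequal", ]
  expect_lt(abs(mean(uneq$protest == "against_small") - 0.6),
            tol(0.6, nrow(uneq)))
  expect_lt(abs(mean(agreed$change_of_tray) - 0.15),
            tol(0.15, nrow(agreed)))
})

test_that("random dyads hit chance-level unequal choice on the study scale", {
  withr::local_seed(6)
  means <- replicate(200, {
    ds <- simulate_dataset(null_config(sample.int(1e8, 1)))
    mean(summarize_dyads(ds)$prop_unequal)
  })
  # grand mean over 200 replicates of 12 dyads x 4 trials
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.5), 3 * se)
})

test_that("mixtures draw one component per dyad at creation", {
  mix <- strategy_spec(
    "mixture",
    components = list(strategy_spec("monopolist"),
                      strategy_spec("equal_preferrer")),
    weights = c(0.5, 0.5)
  )
  cfg <- simulation_config(design_exp1(),
                           groups = study_groups(mix, n_per_age = 24),
                           seed = 13)
  ds <- simulate_dataset(cfg)
  sm <- summarize_dyads(ds)
  # every dyad is purely one or the other, never a within-dyad blend
  expect_true(all(sm$n_unequal %in% c(0L, 4L)))
  kinds <- attr(ds, "strategy_kinds")
  expect_setequal(unique(kinds), c("monopolist", "equal_preferrer"))
  expect_error(
    strategy_spec("mixture", components = list(strategy_spec("random")),
                  weights = 0.5),
    "sum to 1"
  )
})

test_that("calibration experiment reports rejection rates with their errors", {
  cfg <- null_config(1)
  tab <- calibration_experiment(
    40, cfg, analysis_config(seed = 17, n_reps = 400),
    alpha = c(0.05, 0.5)
  )
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$rejection_rate >= 0 & tab$rejection_rate <= 1))
  expect_true(all(tab$n_reject == tab$rejection_rate * 40))
  # power against an all-monopolist population is total
  mono_cfg <- simulation_config(
    design_exp1(), groups = study_groups(strategy_spec("monopolist")),
    seed = 1
  )
  power <- calibration_experiment(
    10, mono_cfg, analysis_config(seed = 19, n_reps = 400)
  )
  expect_equal(
    power$rejection_rate[power$test == "pure_strategy"], 1
  )
})

test_that("recovery experiment recovers deterministic strategies exactly", {
  mix <- strategy_spec(
    "mixture",
    components = list(strategy_spec("monopolist"),
                      strategy_spec("equal_preferrer"),
                      strategy_spec("alternator")),
    weights = c(1, 1, 1) / 3
  )
  cfg <- simulation_config(design_exp1(),
                           groups = study_groups(mix, n_per_age = 12),
                           seed = 5)
  rec <- recovery_experiment(cfg, n_replicates = 3)
  expect_true(all(rec$recovery$recovery_rate == 1))
  # the confusion table is diagonal
  expect_true(all(
    rec$confusion$pattern ==
      c(monopolist = "inequality", equal_preferrer = "equality",
        alternator = "reciprocal")[rec$confusion$strategy]
  ))

  # random dyads have no true label
  rnd <- recovery_experiment(null_config(3))
  expect_true(is.na(rnd$recovery$recovery_rate[
    rnd$recovery$strategy == "random"
  ]))
})
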