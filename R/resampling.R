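#' Simulate random tray choices under the null
#'
#' Draws, for each dyad, the number of unequal-tray choices a dyad making
#' fair-coin decisions would produce, with the number of decisions equal to
#' that dyad's observed number of successful trials. This is the building
#' block of the null distributions of [pure_strategy_test()] and
#' [common_strategy_test()]. Uses the current RNG state; seed it (e.g. via
#' [withr::with_seed()]) for reproducibility.
#'
#' @param success_counts Integer vector of per-dyad successful-trial counts,
#'   all at least 1.
#' @param n_reps Number of replicate simulations.
#' @return An integer matrix, `length(success_counts)` rows by `n_reps`
#'   columns, of simulated unequal-choice counts.
#' @export
simulate_null_choices <- function(success_counts, n_reps = 1L) {
  if (length(success_counts) == 0) {
    abort("`success_counts` must contain at least one dyad.")
  }
  if (anyNA(success_counts) || any(success_counts < 1) ||
      any(success_counts != round(success_counts))) {
    abort("`success_counts` must be integers >= 1.")
  }
  n_dyads <- length(success_counts)
  matrix(
    rbinom(n_dyads * n_reps, rep(success_counts, n_reps), 0.5),
    nrow = n_dyads, ncol = n_reps
  )
}

#' Monte Carlo p-value from null draws
#'
#' Significance is the proportion of simulations whose statistic lies at
#' least as far from the reference value as the observed statistic does
#' (non-strict comparison). The `"plain"` convention returns `b/m`; the
#' `"plus_one"` convention returns `(b+1)/(m+1)`, which cannot be exactly
#' zero.
#'
#' @param observed Observed statistic.
#' @param null_draws Numeric vector of simulated statistics.
#' @param reference The null expectation the distance is measured from.
#' @param convention `"plain"` or `"plus_one"`.
#' @return A p-value in \[0, 1\].
#' @examples
#' mc_p_value(0.4, c(0.1, 0.2, 0.5), reference = 0)
#' @export
mc_p_value <- function(observed, null_draws, reference = 0,
                       convention = c("plain", "plus_one")) {
  convention <- match.arg(convention)
  if (length(null_draws) == 0) abort("`null_draws` must be non-empty.")
  obs_dist <- abs(observed - reference)
  b <- sum(abs(null_draws - reference) >= obs_dist)
  m <- length(null_draws)
  if (convention == "plain") b / m else (b + 1) / (m + 1)
}

mc_test <- function(test_name, observed, null_stats, reference, config,
                    n_dyads_included, n_dyads_excluded) {
  p <- mc_p_value(observed, null_stats, reference, config$p_convention)
  structure(
    list(
      test_name = test_name,
      observed_statistic = observed,
      reference = reference,
      n_reps = config$n_reps,
      p_value = p,
      p_convention = config$p_convention,
      seed = config$seed,
      null_summary = c(
        mean = mean(null_stats),
        quantile(null_stats, c(0.025, 0.25, 0.5, 0.75, 0.975))
      ),
      n_dyads_included = n_dyads_included,
      n_dyads_excluded = n_dyads_excluded
    ),
    class = "mc_test"
  )
}

#' @export
print.mc_test <- function(x, ...) {
  cat(sprintf(
    "<mc_test> %s: statistic = %.4f, p = %.4g (%s, %d reps, seed %d)\n",
    x$test_name, x$observed_statistic, x$p_value, x$p_convention,
    x$n_reps, x$seed
  ))
  cat(sprintf("  %d dyads included, %d excluded (no successful trial)\n",
              x$n_dyads_included, x$n_dyads_excluded))
  invisible(x)
}

prop_unequal_per_dyad <- function(dataset) {
  sm <- summarize_dyads(dataset)
  list(
    included = sm[sm$n_success >= 1, ],
    n_excluded = sum(sm$n_success == 0)
  )
}

#' Monte Carlo test for pure tray-choice strategies
#'
#' Tests whether dyads choose between the two trays non-randomly, in
#' either direction. The statistic is the mean, across dyads, of each
#' dyad's absolute deviation from 50% unequal-tray choices. The null
#' distribution is built by simulating every dyad as a fair coin over its
#' observed number of successful trials ([simulate_null_choices()]),
#' repeated `n_reps` times; significance is the proportion of simulations
#' with a statistic at least as large as observed. A significant result
#' means dyads had pure strategies — consistent preferences for one tray —
#' though not necessarily the same tray across dyads.
#'
#' @param dataset A [dyad_dataset()].
#' @param config An [analysis_config()]; supplies seed, `n_reps` and the
#'   p-value convention.
#' @return An `mc_test` object.
#' @seealso [common_strategy_test()] for a shared direction across dyads.
#' @export
pure_strategy_test <- function(dataset, config) {
  run_mc_strategy_test(dataset, config, "pure_strategy")
}

#' Monte Carlo test for a common tray-choice strategy
#'
#' Tests whether dyads lean the same way: the statistic is the mean across
#' dyads of the proportion of successful trials on the unequal tray, and
#' significance is the proportion of null simulations whose mean lies at
#' least as far from the 50% chance expectation as the observed mean
#' (two-sided distance). Significant and above 0.5 means most dyads
#' favoured the unequal tray; dyads with strong but opposite preferences
#' cancel out here while still registering in [pure_strategy_test()].
#'
#' @inheritParams pure_strategy_test
#' @return An `mc_test` object.
#' @export
common_strategy_test <- function(dataset, config) {
  run_mc_strategy_test(dataset, config, "common_strategy")
}

run_mc_strategy_test <- function(dataset, config, test_name) {
  stopifnot(inherits(dataset, "dyad_dataset"))
  if (!inherits(config, "analysis_config")) {
    abort("`config` must be an analysis_config (the seed is mandatory).")
  }
  parts <- prop_unequal_per_dyad(dataset)
  inc <- parts$included
  if (nrow(inc) == 0) {
    abort("No dyad has a successful trial; the Monte Carlo test is undefined.")
  }
  stat_fun <- switch(test_name,
    pure_strategy = function(props) mean(abs(props - 0.5)),
    common_strategy = function(props) mean(props)
  )
  reference <- switch(test_name, pure_strategy = 0, common_strategy = 0.5)
  observed <- stat_fun(inc$prop_unequal)
  k <- inc$n_success
  null_stats <- withr::with_seed(config$seed, {
    sims <- simulate_null_choices(k, n_reps = config$n_reps)
    props <- sims / k # recycles k down the rows
    if (test_name == "pure_strategy") {
      colMeans(abs(props - 0.5))
    } else {
      colMeans(props)
    }
  })
  mc_test(
    test_name, observed, null_stats, reference, config,
    n_dyads_included = nrow(inc), n_dyads_excluded = parts$n_excluded
  )
}
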