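#' Calibration experiment for the Monte Carlo strategy tests
#'
#' Repeatedly simulates datasets from `config`, runs both
#' [pure_strategy_test()] and [common_strategy_test()] on each, and
#' reports rejection proportions at the requested alpha levels with Monte
#' Carlo standard errors. With a `random` strategy the configuration is
#' null-true and the rejection rate estimates the tests' attained type-I
#' error; with any other strategy it estimates power.
#'
#' Per-replicate seeds are drawn reproducibly from `analysis$seed`, so the
#' whole experiment is a pure function of its arguments.
#'
#' @param n_replicates Number of replicate datasets.
#' @param config A [simulation_config()] (its own seed is ignored; seeding
#'   is governed by `analysis$seed`).
#' @param analysis An [analysis_config()] used for every test run.
#' @param alpha Numeric vector of significance levels.
#' @return A tibble: `test`, `alpha`, `n_replicates`, `n_reject`,
#'   `rejection_rate`, `mc_se` (binomial standard error of the rate).
#' @examples
#' \donttest{
#' cfg <- simulation_config(
#'   design_exp1(),
#'   groups = study_groups(strategy_spec("random")), seed = 1
#' )
#' calibration_experiment(50, cfg, analysis_config(seed = 1, n_reps = 500))
#' }
#' @export
calibration_experiment <- function(n_replicates, config, analysis,
                                   alpha = 0.05) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(analysis, "analysis_config"))
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  seeds <- withr::with_seed(
    analysis$seed,
    matrix(sample.int(.Machine$integer.max, 3 * n_replicates),
           ncol = 3)
  )
  p_vals <- matrix(NA_real_, nrow = n_replicates, ncol = 2,
                   dimnames = list(NULL, c("pure_strategy", "common_strategy")))
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- seeds[r, 1]
    ds <- simulate_dataset(cfg_r)
    a_pure <- analysis
    a_pure$seed <- seeds[r, 2]
    a_common <- analysis
    a_common$seed <- seeds[r, 3]
    p_vals[r, 1] <- pure_strategy_test(ds, a_pure)$p_value
    p_vals[r, 2] <- common_strategy_test(ds, a_common)$p_value
  }
  tidyr::expand_grid(
    test = colnames(p_vals), alpha = alpha
  ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n_replicates = n_replicates,
      n_reject = sum(p_vals[, .data$test] <= .data$alpha),
      rejection_rate = .data$n_reject / n_replicates,
      mc_se = sqrt(.data$rejection_rate * (1 - .data$rejection_rate) /
                     n_replicates)
    ) |>
    dplyr::ungroup()
}

# Which pattern label each deterministic generating strategy should recover.
.expected_pattern <- c(
  monopolist = "inequality",
  equal_preferrer = "equality",
  alternator = "reciprocal"
)

#' Strategy-recovery experiment
#'
#' Simulates replicate datasets, classifies every dyad with
#' [classify_dyads()], and cross-tabulates the generating strategy kind
#' against the assigned pattern label. For kinds with a defined target
#' label (monopolist -> inequality, equal_preferrer -> equality,
#' alternator -> reciprocal) a recovery rate is reported; for `random`
#' dyads there is no true label and the rate is `NA`.
#'
#' @param config A [simulation_config()]; its seed governs the experiment.
#' @param tau Classification threshold, see [classify_dyads()].
#' @param n_replicates Number of replicate datasets (default 1).
#' @return A list with `confusion` (tibble: `strategy`, `pattern`, `n`)
#'   and `recovery` (tibble: `strategy`, `n_dyads`, `n_recovered`,
#'   `recovery_rate`).
#' @examples
#' cfg <- simulation_config(
#'   design_exp1(),
#'   groups = study_groups(strategy_spec("alternator")), seed = 1
#' )
#' recovery_experiment(cfg)
#' @export
recovery_experiment <- function(config, tau = 0.66, n_replicates = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- withr::with_seed(
    config$seed,
    sample.int(.Machine$integer.max, n_replicates)
  )
  pieces <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- seeds[r]
    ds <- simulate_dataset(cfg_r)
    kinds <- attr(ds, "strategy_kinds")
    labelled <- classify_dyads(summarize_dyads(ds), tau = tau)
    pieces[[r]] <- tibble::tibble(
      strategy = unname(kinds[labelled$dyad_id]),
      pattern = as.character(labelled$pattern)
    )
  }
  all_labels <- dplyr::bind_rows(pieces)
  confusion <- dplyr::count(all_labels, .data$strategy, .data$pattern)
  recovery <- all_labels |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(
      n_dyads = dplyr::n(),
      n_recovered = if (.data$strategy[1] %in% names(.expected_pattern)) {
        sum(.data$pattern == .expected_pattern[[.data$strategy[1]]])
      } else {
        NA_integer_
      },
      recovery_rate = .data$n_recovered / .data$n_dyads,
      .groups = "drop"
    )
  list(confusion = confusion, recovery = recovery)
}
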