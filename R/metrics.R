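#' Per-dyad summary measures
#'
#' Reduces each dyad's trials to the counts and proportions every
#' downstream test consumes. Proportions are computed per dyad first (the
#' dyad is the unit of analysis); measures whose denominator is zero are
#' returned as `NA` and flagged, never as zero.
#'
#' Denominator conventions, by field:
#' * `prop_unequal`, `prop_equal`: successful trials (`n_success`) — choice
#'   proportions are defined only where a tray was actually obtained;
#' * `protest_prop`: all trials — protests are coded from room entry,
#'   whatever the eventual outcome;
#' * `change_prop`: successful trials — an outcome can only be attributed
#'   to a change of tray where there is an outcome;
#' * `prop_diff`, `highest_earner_prop`: total rewards, undefined when
#'   `n_success = 0`.
#'
#' @param dataset A [dyad_dataset()].
#' @return A tibble with one row per dyad: covariates, `n_trials`,
#'   `n_agreed`, `n_success`, `n_equal`, `n_unequal`, `big_count_a`,
#'   `big_count_b`, `rewards_a`, `rewards_b`, `abs_diff`, `prop_diff`,
#'   `prop_unequal`, `prop_equal`, `highest_earner_prop`, `protest_prop`,
#'   `change_prop`, and the logical flag `undefined_props` (`TRUE` when
#'   `n_success = 0`).
#' @examples
#' ds <- simulate_dataset(simulation_config(
#'   design_exp1(),
#'   groups = study_groups(strategy_spec("random")), seed = 1
#' ))
#' summarize_dyads(ds)
#' @export
summarize_dyads <- function(dataset) {
  stopifnot(inherits(dataset, "dyad_dataset"))
  tr <- trial_rewards(dataset$trials, dataset$design)
  tr |>
    dplyr::group_by(
      .data$dyad_id, .data$experiment, .data$age_group, .data$gender,
      .data$familiarity
    ) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_agreed = sum(.data$outcome != "no_agreement"),
      n_success = sum(.data$outcome == "success"),
      n_equal = sum(.data$outcome == "success" & .data$tray == "equal"),
      n_unequal = sum(.data$outcome == "success" & .data$tray == "unequal"),
      big_count_a = sum(.data$large_recipient == "A"),
      big_count_b = sum(.data$large_recipient == "B"),
      rewards_a = sum(.data$reward_a),
      rewards_b = sum(.data$reward_b),
      protest_prop = mean(.data$protest != "none"),
      change_prop = ratio_or_na(
        sum(.data$outcome == "success" & .data$change_of_tray),
        sum(.data$outcome == "success")
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      abs_diff = abs(.data$rewards_a - .data$rewards_b),
      prop_diff = ratio_or_na(.data$abs_diff, .data$rewards_a + .data$rewards_b),
      prop_unequal = ratio_or_na(.data$n_unequal, .data$n_success),
      prop_equal = ratio_or_na(.data$n_equal, .data$n_success),
      highest_earner_prop = ratio_or_na(
        pmax(.data$rewards_a, .data$rewards_b),
        .data$rewards_a + .data$rewards_b
      ),
      undefined_props = .data$n_success == 0
    ) |>
    dplyr::relocate(
      dplyr::all_of(c("abs_diff", "prop_diff", "prop_unequal", "prop_equal",
                      "highest_earner_prop")),
      .after = "rewards_b"
    )
}

ratio_or_na <- function(num, den) ifelse(den > 0, num / den, NA_real_)

# Proportion measures summarised at the group level, with the per-dyad
# table column each maps onto.
.group_measures <- c(
  prop_agreed = "prop_agreed",
  prop_success_given_agreed = "prop_success_given_agreed",
  prop_unequal = "prop_unequal",
  prop_equal = "prop_equal",
  prop_diff = "prop_diff",
  highest_earner_prop = "highest_earner_prop",
  protest_prop = "protest_prop",
  change_prop = "change_prop"
)

#' Group-level summaries of per-dyad proportions
#'
#' Averages per-dyad proportion measures within groups defined by any
#' combination of covariates. Percentages are computed per dyad first and
#' then averaged across dyads; dyads whose measure is undefined (zero
#' denominator) are excluded from that measure's mean/SD and counted in
#' `n_excluded`. The SD is the sample (n-1) standard deviation across
#' dyads and is `NA` for singleton groups.
#'
#' @param dataset A [dyad_dataset()].
#' @param grouping Character vector of covariate names to group by; any of
#'   `"experiment"`, `"age_group"`, `"gender"`, `"familiarity"`.
#' @return A long tibble: grouping columns, `measure`, `n_dyads` (dyads with
#'   the measure defined), `n_excluded`, `mean`, `sd`.
#' @examples
#' ds <- simulate_dataset(simulation_config(
#'   design_exp1(),
#'   groups = study_groups(strategy_spec("random")), seed = 1
#' ))
#' summarize_groups(ds, "age_group")
#' @export
summarize_groups <- function(dataset, grouping = "age_group") {
  covars <- c("experiment", "age_group", "gender", "familiarity")
  bad <- setdiff(grouping, covars)
  if (length(bad) > 0) {
    abort(sprintf("Unknown covariate(s): %s. Choose from: %s",
                  toString(bad), toString(covars)))
  }
  per_dyad <- summarize_dyads(dataset) |>
    dplyr::mutate(
      prop_agreed = .data$n_agreed / .data$n_trials,
      prop_success_given_agreed = ratio_or_na(.data$n_success, .data$n_agreed)
    )
  per_dyad |>
    tidyr::pivot_longer(
      dplyr::all_of(unname(.group_measures)),
      names_to = "measure", values_to = "value"
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, "measure")))) |>
    dplyr::summarise(
      n_dyads = sum(!is.na(.data$value)),
      n_excluded = sum(is.na(.data$value)),
      mean = if (sum(!is.na(.data$value)) > 0) {
        mean(.data$value, na.rm = TRUE)
      } else {
        NA_real_
      },
      sd = if (sum(!is.na(.data$value)) > 1) {
        sd(.data$value, na.rm = TRUE)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}

#' Highest-earner points for outcome plots
#'
#' For every dyad with at least one successful trial, returns the pair
#' (proportion of successful trials on the unequal tray, proportion of all
#' rewards obtained by the dyad's highest earner). These are the empirical
#' points to plot against the theoretical [monopoly_curve()] and
#' [alternation_curve()].
#'
#' @param dataset A [dyad_dataset()].
#' @return A tibble with columns `dyad_id`, covariates, `prop_unequal`,
#'   `highest_earner_prop`. Dyads with no successful trial are omitted.
#' @export
highest_earner_points <- function(dataset) {
  summarize_dyads(dataset) |>
    dplyr::filter(.data$n_success >= 1) |>
    dplyr::select(dplyr::all_of(c(
      "dyad_id", "experiment", "age_group", "gender", "familiarity",
      "prop_unequal", "highest_earner_prop"
    )))
}
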