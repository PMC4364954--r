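#' First-choice binomial tests
#'
#' For each covariate group, counts the dyads whose first trial's agreed
#' tray was the equal tray and tests that count against a fair-coin null
#' with [binom_two_sided()]. Dyads whose first trial ended in no agreement
#' have no first choice and are excluded from the denominator. The agreed
#' tray counts whether or not the pull succeeded.
#'
#' @param dataset A [dyad_dataset()].
#' @param grouping Covariates defining the groups (default `"age_group"`).
#' @return A tibble: grouping columns, `n_equal_first`, `n_dyads`,
#'   `n_excluded`, `p_value`.
#' @export
first_choice_test <- function(dataset, grouping = "age_group") {
  first <- dataset$trials |>
    dplyr::filter(.data$trial_index == 1)
  first |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n_equal_first = sum(.data$tray == "equal"),
      n_dyads = sum(.data$tray != "none"),
      n_excluded = sum(.data$tray == "none"),
      .groups = "drop"
    ) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      p_value = if (.data$n_dyads > 0) {
        binom_two_sided(.data$n_equal_first, .data$n_dyads)$p_value
      } else {
        NA_real_
      }
    ) |>
    dplyr::ungroup()
}

#' Run the full analysis pipeline
#'
#' Executes every stage of the analysis on a trial dataset, in order:
#' group summaries, the two Monte Carlo strategy tests, the observed vs
#' expected inequality test, first-choice binomial tests, dyad pattern
#' classification, theoretical outcome curves, and negotiation
#' descriptives. Stochastic stages are seeded from `analysis`; the whole
#' report is deterministic given the dataset and configuration.
#'
#' @param dataset A [dyad_dataset()].
#' @param analysis An [analysis_config()].
#' @param grouping Covariates used for grouped summaries and tests
#'   (default `"age_group"`).
#' @return An `analysis_report`: a list with elements `provenance`
#'   (`seed`, `n_reps`, `threshold`, `p_convention`, `design`, `n_dyads`,
#'   `timestamp`), `group_summaries`, `monte_carlo` (`pure`, `common`),
#'   `observed_vs_expected`, `first_choice`, `classification`, `curves`,
#'   `negotiation`, and `warnings` (character vector; excluded dyads and
#'   degenerate tests are listed here).
#' @examples
#' ds <- simulate_dataset(simulation_config(
#'   design_exp1(),
#'   groups = study_groups(strategy_spec("random")), seed = 1
#' ))
#' report <- run_analysis(ds, analysis_config(seed = 1, n_reps = 1000))
#' report$monte_carlo$pure$p_value
#' @export
run_analysis <- function(dataset, analysis, grouping = "age_group") {
  stopifnot(inherits(dataset, "dyad_dataset"),
            inherits(analysis, "analysis_config"))
  warnings <- character(0)
  sm <- summarize_dyads(dataset)
  zero_success <- sm$dyad_id[sm$n_success == 0]
  if (length(zero_success) > 0) {
    warnings <- c(warnings, sprintf(
      "Dyad(s) with no successful trial excluded from choice-based analyses: %s",
      toString(zero_success)
    ))
  }
  mc_pure <- pure_strategy_test(dataset, analysis)
  mc_common <- common_strategy_test(dataset, analysis)
  ove <- observed_vs_expected_test(dataset)
  if (isTRUE(ove$test$degenerate)) {
    warnings <- c(warnings,
                  "Observed vs expected test degenerate: all differences zero.")
  }
  neg <- negotiation_summary(dataset, grouping = grouping)
  if (is.null(neg$change_test)) {
    warnings <- c(warnings,
                  "No dyad produced both outcome types; paired change-of-tray test skipped.")
  }
  warnings <- c(warnings,
                "Protest proportions use all trials as denominator (protests are coded from room entry).")
  cls <- classify_dataset(dataset, tau = analysis$threshold)
  structure(
    list(
      provenance = list(
        seed = analysis$seed, n_reps = analysis$n_reps,
        threshold = analysis$threshold, p_convention = analysis$p_convention,
        design = unclass(dataset$design),
        n_dyads = dplyr::n_distinct(dataset$trials$dyad_id),
        timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
      ),
      group_summaries = summarize_groups(dataset, grouping = grouping),
      monte_carlo = list(pure = mc_pure, common = mc_common),
      observed_vs_expected = ove,
      first_choice = first_choice_test(dataset, grouping = grouping),
      classification = cls,
      curves = curve_table(dataset$design),
      negotiation = neg,
      warnings = warnings
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  %d dyads; seed %d, %d Monte Carlo reps\n",
              x$provenance$n_dyads, x$provenance$seed, x$provenance$n_reps))
  cat(sprintf("  pure strategy:   statistic %.4f, p = %.4g\n",
              x$monte_carlo$pure$observed_statistic,
              x$monte_carlo$pure$p_value))
  cat(sprintf("  common strategy: statistic %.4f, p = %.4g\n",
              x$monte_carlo$common$observed_statistic,
              x$monte_carlo$common$p_value))
  cat(sprintf("  observed vs expected inequality: T = %g, p = %.4g\n",
              x$observed_vs_expected$test$statistic,
              x$observed_vs_expected$test$p_value))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Write an analysis report to JSON
#'
#' Serialises an `analysis_report` to a JSON document. The timestamp is
#' isolated in `provenance$timestamp` so byte comparisons of two reports
#' can mask a single field.
#'
#' @param report An `analysis_report` from [run_analysis()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  stripped <- rapply(
    unclass(report),
    function(x) if (is.factor(x)) as.character(x) else x,
    how = "replace"
  )
  jsonlite::write_json(stripped, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
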