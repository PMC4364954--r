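#' Theoretical highest-earner outcome curves
#'
#' Predicted proportion of all rewards going to a dyad's highest earner as
#' a function of how often the dyad took the unequal tray, under two
#' limiting strategies:
#'
#' * **Monopoly** ([monopoly_curve()]): the same child obtains the large
#'   reward on every unequal-tray success. The highest earner collects
#'   `u*L + (n-u)*E` of the `u*(L+S) + (n-u)*2E` rewards.
#' * **Alternation** ([alternation_curve()]): the children alternate the
#'   large role, so the highest earner collects
#'   `ceiling(u/2)*L + floor(u/2)*S + (n-u)*E`.
#'
#' Both equal 0.5 at `u = 0`; the monopoly curve rises to `L/(L+S)` at
#' `u = n`, while the alternation curve returns to 0.5 whenever `u` is
#' even. Empirical dyads ([highest_earner_points()]) fall between the two.
#'
#' @param u Number of unequal-tray successes, 0..n (vectorised).
#' @param n Total number of successful trials (>= 1).
#' @param design A [tray_design()].
#' @return Highest-earner reward proportion(s) in `[0.5, L/(L+S)]`.
#' @examples
#' monopoly_curve(4, 4, design_exp1()) # 0.75
#' alternation_curve(4, 4, design_exp1()) # 0.5
#' @export
monopoly_curve <- function(u, n, design) {
  check_curve_args(u, n)
  (u * design$L + (n - u) * design$E) /
    (u * (design$L + design$S) + (n - u) * 2 * design$E)
}

#' @rdname monopoly_curve
#' @export
alternation_curve <- function(u, n, design) {
  check_curve_args(u, n)
  (ceiling(u / 2) * design$L + floor(u / 2) * design$S + (n - u) * design$E) /
    (u * (design$L + design$S) + (n - u) * 2 * design$E)
}

check_curve_args <- function(u, n) {
  if (any(is.na(u)) || any(is.na(n)) || any(n < 1)) {
    abort("`n` must be >= 1 (a dyad with no successes has no earner).")
  }
  if (any(u < 0) || any(u > n) || any(u != round(u)) || any(n != round(n))) {
    abort("`u` must be an integer in 0..n.")
  }
}

#' @rdname monopoly_curve
#' @return `curve_table()` returns a tibble with one row per `u = 0..n`:
#'   `u`, `n`, `prop_unequal`, `monopoly_prop`, `alternation_prop`.
#' @export
curve_table <- function(design, n = design$n_test_trials) {
  u <- 0:n
  tibble::tibble(
    u = u, n = n, prop_unequal = u / n,
    monopoly_prop = monopoly_curve(u, n, design),
    alternation_prop = alternation_curve(u, n, design)
  )
}

#' Classify a dyad's allocation pattern
#'
#' Assigns each dyad one of four behavioural patterns from its successful
#' trials, using threshold `tau` (default 0.66, so 2 of 3 successes
#' qualifies as a majority):
#'
#' 1. **equality** — the equal tray was chosen in at least `tau` of the
#'    successful trials;
#' 2. **reciprocal** — at least two unequal-tray successes and both
#'    children obtained the large reward equally often;
#' 3. **inequality** — one child obtained the large reward in at least
#'    `tau` of the successful trials;
#' 4. **mixed** — anything else.
#'
#' Rules are evaluated in that order; dyads with no successful trial are
#' `undetermined`. Requiring two unequal successes for `reciprocal`
#' prevents a single unequal trial from counting as turn taking, and the
#' order resolves the rare collisions (a pattern that is mostly equal with
#' balanced large-role turns reads as equality first).
#'
#' @param summaries A per-dyad summary tibble from [summarize_dyads()]
#'   (or a single row of it).
#' @param tau Majority threshold in (0.5, 1]; compared with `>=`.
#' @return `classify_dyads()`: the input tibble with a `pattern` factor
#'   column (levels inequality, equality, reciprocal, mixed, undetermined).
#' @examples
#' ds <- simulate_dataset(simulation_config(
#'   design_exp1(),
#'   groups = study_groups(strategy_spec("monopolist")), seed = 1
#' ))
#' classify_dyads(summarize_dyads(ds))
#' @export
classify_dyads <- function(summaries, tau = 0.66) {
  if (length(tau) != 1 || is.na(tau) || tau <= 0.5 || tau > 1) {
    abort("`tau` must lie in (0.5, 1].")
  }
  n_success <- summaries$n_success
  big_max <- pmax(summaries$big_count_a, summaries$big_count_b)
  pattern <- dplyr::case_when(
    n_success == 0 ~ "undetermined",
    summaries$n_equal / n_success >= tau ~ "equality",
    summaries$n_unequal >= 2 &
      summaries$big_count_a == summaries$big_count_b ~ "reciprocal",
    big_max / n_success >= tau ~ "inequality",
    .default = "mixed"
  )
  summaries$pattern <- factor(
    pattern,
    levels = c("inequality", "equality", "reciprocal", "mixed", "undetermined")
  )
  summaries
}

#' Pattern counts per group
#'
#' Applies [classify_dyads()] and tabulates the pattern labels per
#' (experiment, age group) cell.
#'
#' @param dataset A [dyad_dataset()].
#' @param tau Majority threshold, see [classify_dyads()].
#' @return A list with `dyads` (per-dyad summaries with `pattern`) and
#'   `counts` (tibble: `experiment`, `age_group`, one column per label,
#'   rows summing to the number of dyads in the cell).
#' @export
classify_dataset <- function(dataset, tau = 0.66) {
  labelled <- classify_dyads(summarize_dyads(dataset), tau = tau)
  counts <- labelled |>
    dplyr::count(.data$experiment, .data$age_group, .data$pattern,
                 .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "pattern", values_from = "n",
                       values_fill = 0L) |>
    dplyr::semi_join(labelled, by = c("experiment", "age_group"))
  list(dyads = labelled, counts = counts)
}

#' Negotiation descriptives
#'
#' Summarises how dyads negotiated before pulling: per-dyad protest
#' proportions, the split of protests into protests against the small
#' amount versus against the equal tray, and — separately for equal and
#' unequal outcomes — the proportion of successful trials that were
#' immediately accepted (no protest, no change of tray) and the proportion
#' that resulted from a change of tray. Change-of-tray proportions for the
#' two outcome types are compared with a paired [wilcoxon_exact()] over
#' the dyads that produced both outcome types; dyads lacking one type are
#' excluded from the pairing and counted.
#'
#' @param dataset A [dyad_dataset()].
#' @param grouping Covariates for the group means (default `"age_group"`).
#' @return A list of class `negotiation_summary`:
#'   * `per_dyad`: per-dyad tibble (`protest_prop`, `equal_immediate`,
#'     `equal_change`, `unequal_immediate`, `unequal_change`, `n_protests`,
#'     `protests_against_small`, `protests_against_equal`);
#'   * `group`: group means of those proportions (undefined cells dropped
#'     per measure), plus the pooled protest split per group;
#'   * `change_test`: the paired exact test on (equal change proportion -
#'     unequal change proportion), or `NULL` if no dyad has both outcomes;
#'   * `n_paired`, `n_unpaired`: dyads with/without both outcome types.
#' @export
negotiation_summary <- function(dataset, grouping = "age_group") {
  tr <- dataset$trials
  per_dyad <- tr |>
    dplyr::group_by(
      .data$dyad_id, .data$experiment, .data$age_group, .data$gender,
      .data$familiarity
    ) |>
    dplyr::summarise(
      protest_prop = mean(.data$protest != "none"),
      n_protests = sum(.data$protest != "none"),
      protests_against_small = sum(.data$protest == "against_small"),
      protests_against_equal = sum(.data$protest == "against_equal"),
      equal_immediate = ratio_or_na(
        sum(.data$outcome == "success" & .data$tray == "equal" &
              .data$protest == "none" & !.data$change_of_tray),
        sum(.data$outcome == "success" & .data$tray == "equal")
      ),
      equal_change = ratio_or_na(
        sum(.data$outcome == "success" & .data$tray == "equal" &
              .data$change_of_tray),
        sum(.data$outcome == "success" & .data$tray == "equal")
      ),
      unequal_immediate = ratio_or_na(
        sum(.data$outcome == "success" & .data$tray == "unequal" &
              .data$protest == "none" & !.data$change_of_tray),
        sum(.data$outcome == "success" & .data$tray == "unequal")
      ),
      unequal_change = ratio_or_na(
        sum(.data$outcome == "success" & .data$tray == "unequal" &
              .data$change_of_tray),
        sum(.data$outcome == "success" & .data$tray == "unequal")
      ),
      .groups = "drop"
    )

  measures <- c("protest_prop", "equal_immediate", "equal_change",
                "unequal_immediate", "unequal_change")
  group <- per_dyad |>
    tidyr::pivot_longer(dplyr::all_of(measures),
                        names_to = "measure", values_to = "value") |>
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
  protest_split <- per_dyad |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n_protests = sum(.data$n_protests),
      share_against_small = ratio_or_na(sum(.data$protests_against_small),
                                        sum(.data$n_protests)),
      share_against_equal = ratio_or_na(sum(.data$protests_against_equal),
                                        sum(.data$n_protests)),
      .groups = "drop"
    )

  paired <- per_dyad[!is.na(per_dyad$equal_change) &
                       !is.na(per_dyad$unequal_change), ]
  change_test <- if (nrow(paired) > 0) {
    wilcoxon_exact(paired$equal_change - paired$unequal_change)
  } else {
    NULL
  }
  structure(
    list(
      per_dyad = per_dyad, group = group, protest_split = protest_split,
      change_test = change_test,
      n_paired = nrow(paired), n_unpaired = nrow(per_dyad) - nrow(paired)
    ),
    class = "negotiation_summary"
  )
}

#' @export
print.negotiation_summary <- function(x, ...) {
  cat(sprintf(
    "<negotiation_summary> %d dyads (%d with both outcome types)\n",
    nrow(x$per_dyad), x$n_paired
  ))
  if (!is.null(x$change_test)) {
    cat("Paired change-of-tray comparison (equal - unequal):\n")
    print(x$change_test)
  }
  invisible(x)
}
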