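#' Construct and validate a dyad dataset
#'
#' A dyad dataset couples a [tray_design()] with a tibble of coded trials,
#' one row per trial. Each row carries the dyad's covariates (experiment,
#' age group, gender, familiarity) together with the trial's coded outcome:
#' whether the dyad agreed and succeeded, which tray was chosen, which child
#' sat at the large plate on a successful unequal-tray trial, whether a
#' protest occurred during the negotiation phase, and whether the final tray
#' resulted from a change of tray.
#'
#' Structural rules enforced on every record:
#' * `tray == "none"` exactly when `outcome == "no_agreement"`;
#' * `large_recipient != "none"` exactly when the trial is a successful
#'   unequal-tray trial;
#' * trial indices within a dyad run 1..`n_test_trials` without gaps or
#'   duplicates, and covariates are constant within a dyad.
#'
#' @param design A [tray_design()].
#' @param trials A data frame with the columns listed in [read_trials()].
#' @return A validated `dyad_dataset` object: a list with elements `design`
#'   and `trials` (a tibble in dyad-then-trial order).
#' @examples
#' ds <- dyad_dataset(design_exp1(), tibble::tibble(
#'   dyad_id = "d1", experiment = 1L, age_group = "5", gender = "F",
#'   familiarity = "familiar", trial_index = 1:4, outcome = "success",
#'   tray = "equal", large_recipient = "none", protest = "none",
#'   change_of_tray = FALSE
#' ))
#' @export
dyad_dataset <- function(design, trials) {
  if (!inherits(design, "tray_design")) abort("`design` must be a tray_design.")
  trials <- tibble::as_tibble(trials)
  missing_cols <- setdiff(.trial_columns, names(trials))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing trial columns: %s", toString(missing_cols)))
  }
  trials <- trials[.trial_columns]
  trials$dyad_id <- as.character(trials$dyad_id)
  trials$experiment <- as.integer(trials$experiment)
  trials$trial_index <- as.integer(trials$trial_index)
  for (col in c("age_group", "gender", "familiarity", "outcome", "tray",
                "large_recipient", "protest")) {
    trials[[col]] <- as.character(trials[[col]])
  }
  trials$change_of_tray <- as.logical(trials$change_of_tray)
  validate_trials(trials, design)
  trials <- dplyr::arrange(trials, match(.data$dyad_id, unique(trials$dyad_id)),
                           .data$trial_index)
  structure(list(design = design, trials = trials), class = "dyad_dataset")
}

#' @export
print.dyad_dataset <- function(x, ...) {
  cat(sprintf(
    "<dyad_dataset> %d dyads, %d trials; equal (%d,%d) vs unequal (%d,%d)\n",
    dplyr::n_distinct(x$trials$dyad_id), nrow(x$trials),
    x$design$E, x$design$E, x$design$L, x$design$S
  ))
  invisible(x)
}

# Row- and dyad-level validation. Errors name the first offending row and
# field so malformed files are debuggable; nothing is ever coerced silently.
validate_trials <- function(trials, design) {
  fail_row <- function(i, field, msg) {
    abort(sprintf("Invalid trial data (row %d, field `%s`): %s", i, field, msg))
  }
  check_enum <- function(col, allowed) {
    bad <- which(is.na(trials[[col]]) | !(trials[[col]] %in% allowed))
    if (length(bad) > 0) {
      fail_row(bad[1], col, sprintf(
        "value %s is not one of {%s}",
        if (is.na(trials[[col]][bad[1]])) "NA"
        else sprintf("'%s'", trials[[col]][bad[1]]),
        toString(allowed)
      ))
    }
  }
  check_enum("outcome", .outcomes)
  check_enum("tray", .trays)
  check_enum("large_recipient", .recipients)
  check_enum("protest", .protests)
  check_enum("age_group", .age_groups)
  check_enum("gender", .genders)
  check_enum("familiarity", .familiarities)

  bad <- which(is.na(trials$experiment) | !(trials$experiment %in% c(1L, 2L)))
  if (length(bad) > 0) fail_row(bad[1], "experiment", "must be 1 or 2")
  bad <- which(is.na(trials$change_of_tray))
  if (length(bad) > 0) fail_row(bad[1], "change_of_tray", "must be true/false")
  bad <- which(is.na(trials$trial_index) | trials$trial_index < 1L |
                 trials$trial_index > design$n_test_trials)
  if (length(bad) > 0) {
    fail_row(bad[1], "trial_index",
             sprintf("must lie in 1..%d", design$n_test_trials))
  }

  # tray = none iff no_agreement
  bad <- which((trials$tray == "none") != (trials$outcome == "no_agreement"))
  if (length(bad) > 0) {
    fail_row(bad[1], "tray",
             "tray must be 'none' exactly when outcome is 'no_agreement'")
  }
  # large_recipient set iff successful unequal trial
  is_unequal_success <- trials$outcome == "success" & trials$tray == "unequal"
  bad <- which((trials$large_recipient != "none") != is_unequal_success)
  if (length(bad) > 0) {
    fail_row(bad[1], "large_recipient",
             paste("large_recipient must be 'A' or 'B' exactly on successful",
                   "unequal-tray trials, 'none' otherwise"))
  }

  # per-dyad structure
  for (id in unique(trials$dyad_id)) {
    sub <- trials[trials$dyad_id == id, ]
    idx <- sort(sub$trial_index)
    if (!identical(idx, seq_len(design$n_test_trials))) {
      abort(sprintf(
        "Invalid trial data (dyad '%s'): trial indices must be 1..%d without gaps or duplicates, got {%s}",
        id, design$n_test_trials, toString(sub$trial_index)
      ))
    }
    for (col in c("experiment", "age_group", "gender", "familiarity")) {
      if (dplyr::n_distinct(sub[[col]]) != 1) {
        abort(sprintf(
          "Invalid trial data (dyad '%s', field `%s`): covariates must be constant within a dyad",
          id, col
        ))
      }
    }
  }
  invisible(trials)
}

#' Per-trial rewards
#'
#' Computes the number of rewards obtained by each child on each trial.
#' Only successful trials yield rewards: the equal tray gives (`E`, `E`),
#' the unequal tray gives (`L`, `S`) with the large share to the coded
#' large recipient. Every other outcome yields (0, 0) — each child keeps
#' only what their plate held on a retrieved board.
#'
#' @param trials A trial tibble (as in a [dyad_dataset()]).
#' @param design A [tray_design()].
#' @return The input tibble with integer columns `reward_a` and `reward_b`
#'   appended.
#' @examples
#' ds <- simulate_dataset(simulation_config(
#'   design_exp1(),
#'   groups = study_groups(strategy_spec("random")), seed = 1
#' ))
#' trial_rewards(ds$trials, ds$design)
#' @export
trial_rewards <- function(trials, design) {
  success <- trials$outcome == "success"
  equal <- success & trials$tray == "equal"
  uneq <- success & trials$tray == "unequal"
  reward_a <- reward_b <- integer(nrow(trials))
  reward_a[equal] <- design$E
  reward_b[equal] <- design$E
  a_big <- uneq & trials$large_recipient == "A"
  b_big <- uneq & trials$large_recipient == "B"
  reward_a[a_big] <- design$L
  reward_b[a_big] <- design$S
  reward_a[b_big] <- design$S
  reward_b[b_big] <- design$L
  trials$reward_a <- reward_a
  trials$reward_b <- reward_b
  trials
}
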