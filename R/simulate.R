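#' Dyad strategy specification
#'
#' Describes the stochastic behaviour of a simulated dyad. A trial unfolds
#' as: (1) with probability `p_no_agreement` the dyad fails to agree
#' (outcome `no_agreement`, no tray); (2) otherwise a tray is agreed —
#' unequal with probability `p_unequal`; (3) with probability
#' `p_coordination_failure` the agreed pull fails (outcome
#' `unsuccessful_agreement`, the agreed tray is retained); (4) on a
#' successful unequal trial the large reward goes to the dyad's dominant
#' child with probability `p_dominant_large` — except for the
#' `alternator` kind, where the large role alternates deterministically
#' across unequal successes (failed trials do not advance the turn).
#' Protests are drawn per agreed-tray context (`against_small` on unequal
#' trials, `against_equal` on equal trials; none on no-agreement trials)
#' and change-of-tray flags are independent draws on agreed trials.
#'
#' Kinds preset the choice parameters:
#' * `random`: fair-coin tray choice (`p_unequal = 0.5`), random large role;
#' * `monopolist`: always unequal, dominant child always at the large plate;
#' * `equal_preferrer`: always the equal tray;
#' * `alternator`: always unequal, strict turn taking;
#' * `mixture`: each dyad draws one component spec (with `components` and
#'   `weights`) at creation and keeps it for all its trials.
#'
#' Explicit arguments override the preset.
#'
#' @param kind One of `"random"`, `"monopolist"`, `"equal_preferrer"`,
#'   `"alternator"`, `"mixture"`.
#' @param p_unequal Probability an agreed trial targets the unequal tray.
#' @param p_dominant_large Probability the dominant child takes the large
#'   reward on an unequal success (ignored for `alternator`).
#' @param p_no_agreement Per-trial probability of no agreement.
#' @param p_coordination_failure Probability an agreed pull fails.
#' @param protest_against_small Protest probability on unequal-tray trials.
#' @param protest_against_equal Protest probability on equal-tray trials.
#' @param p_change_of_tray Probability an agreed trial is coded as a change
#'   of tray.
#' @param components,weights For `kind = "mixture"`: a list of
#'   `strategy_spec`s and their sampling weights (summing to 1).
#' @return A `strategy_spec` object.
#' @examples
#' strategy_spec("monopolist")
#' strategy_spec("random", p_no_agreement = 0.05)
#' @export
strategy_spec <- function(kind = c("random", "monopolist", "equal_preferrer",
                                   "alternator", "mixture"),
                          p_unequal = NULL, p_dominant_large = NULL,
                          p_no_agreement = 0, p_coordination_failure = 0,
                          protest_against_small = 0,
                          protest_against_equal = 0,
                          p_change_of_tray = 0,
                          components = NULL, weights = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    random = list(p_unequal = 0.5, p_dominant_large = 0.5),
    monopolist = list(p_unequal = 1, p_dominant_large = 1),
    equal_preferrer = list(p_unequal = 0, p_dominant_large = 0.5),
    alternator = list(p_unequal = 1, p_dominant_large = NA_real_),
    mixture = list(p_unequal = NA_real_, p_dominant_large = NA_real_)
  )
  p_unequal <- p_unequal %||% defaults$p_unequal
  p_dominant_large <- p_dominant_large %||% defaults$p_dominant_large
  probs <- c(
    p_no_agreement = p_no_agreement,
    p_coordination_failure = p_coordination_failure,
    protest_against_small = protest_against_small,
    protest_against_equal = protest_against_equal,
    p_change_of_tray = p_change_of_tray
  )
  if (kind != "mixture") probs <- c(probs, p_unequal = p_unequal)
  bad <- names(probs)[is.na(probs) | probs < 0 | probs > 1]
  if (length(bad) > 0) {
    abort(sprintf("Probabilities must lie in [0, 1]: %s", toString(bad)))
  }
  if (kind == "mixture") {
    if (is.null(components) || is.null(weights) ||
        length(components) != length(weights) || length(components) == 0) {
      abort("A mixture needs `components` and matching `weights`.")
    }
    if (!all(vapply(components, inherits, logical(1), "strategy_spec"))) {
      abort("Every mixture component must be a strategy_spec.")
    }
    if (any(vapply(components, function(s) s$kind == "mixture", logical(1)))) {
      abort("Mixture components cannot themselves be mixtures.")
    }
    if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
      abort("`weights` must be non-negative and sum to 1.")
    }
  }
  structure(
    list(
      kind = kind, p_unequal = p_unequal,
      p_dominant_large = p_dominant_large,
      p_no_agreement = p_no_agreement,
      p_coordination_failure = p_coordination_failure,
      protest_against_small = protest_against_small,
      protest_against_equal = protest_against_equal,
      p_change_of_tray = p_change_of_tray,
      components = components, weights = weights
    ),
    class = "strategy_spec"
  )
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf("<strategy_spec> %s", x$kind))
  if (x$kind != "mixture") {
    cat(sprintf(" (p_unequal = %.2f)", x$p_unequal))
  } else {
    cat(sprintf(" of %d components", length(x$components)))
  }
  cat("\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Couples a [tray_design()] with a list of dyad groups and a seed. Each
#' group entry fixes a covariate combination, the number of dyads in it,
#' and the [strategy_spec()] those dyads follow.
#'
#' @param design A [tray_design()].
#' @param groups A list of group entries, each a list with elements
#'   `experiment`, `age_group`, `gender`, `familiarity`, `n_dyads`,
#'   `strategy`. See [study_groups()] for the study-shaped layout.
#' @param seed Integer seed (mandatory).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(design, groups, seed) {
  if (!inherits(design, "tray_design")) abort("`design` must be a tray_design.")
  if (missing(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be supplied as a single integer.")
  }
  if (length(groups) == 0) abort("`groups` must contain at least one entry.")
  for (g in groups) {
    needed <- c("experiment", "age_group", "gender", "familiarity",
                "n_dyads", "strategy")
    missing_fields <- setdiff(needed, names(g))
    if (length(missing_fields) > 0) {
      abort(sprintf("Group entry is missing fields: %s",
                    toString(missing_fields)))
    }
    if (g$n_dyads < 1) abort("Each group needs `n_dyads` >= 1.")
    if (!inherits(g$strategy, "strategy_spec")) {
      abort("Each group's `strategy` must be a strategy_spec.")
    }
  }
  structure(
    list(design = design, groups = groups, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Study-shaped group layout
#'
#' Builds the group list of one experiment arm as tested in the study:
#' 12 same-sex dyads per age group (3.5- and 5-year-olds), balanced by
#' gender and familiarity (3 dyads per gender-by-familiarity cell).
#'
#' @param strategy A [strategy_spec()] applied to every group, or a named
#'   list with one spec per age group (names `"3.5"` and `"5"`).
#' @param experiment 1 or 2.
#' @param n_per_age Dyads per age group (default 12).
#' @return A list of group entries for [simulation_config()].
#' @examples
#' cfg <- simulation_config(
#'   design_exp1(),
#'   groups = study_groups(strategy_spec("random")), seed = 1
#' )
#' @export
study_groups <- function(strategy, experiment = 1L, n_per_age = 12L) {
  if (inherits(strategy, "strategy_spec")) {
    strategy <- list("3.5" = strategy, "5" = strategy)
  }
  if (!all(.age_groups %in% names(strategy))) {
    abort('`strategy` must be a strategy_spec or a named list for "3.5" and "5".')
  }
  cells <- expand.grid(
    gender = .genders, familiarity = .familiarities,
    stringsAsFactors = FALSE
  )
  per_cell <- diff(round(seq(0, n_per_age, length.out = nrow(cells) + 1)))
  groups <- list()
  for (ag in .age_groups) {
    for (i in seq_len(nrow(cells))) {
      if (per_cell[i] == 0) next
      groups[[length(groups) + 1]] <- list(
        experiment = as.integer(experiment), age_group = ag,
        gender = cells$gender[i], familiarity = cells$familiarity[i],
        n_dyads = per_cell[i], strategy = strategy[[ag]]
      )
    }
  }
  groups
}

#' Simulate a dataset
#'
#' Generates a fully coded trial table from a [simulation_config()],
#' reproducibly from its seed, and returns it as a validated
#' [dyad_dataset()]. Dyad ids are `d01`, `d02`, ... in group order; within
#' a dyad the dominant child (the one favoured by `p_dominant_large`, and
#' the one who starts an alternator's turn cycle) is child A.
#'
#' @param config A [simulation_config()].
#' @return A [dyad_dataset()]. The per-dyad generating strategy kind is
#'   attached as attribute `"strategy_kinds"` (named by dyad id) for use in
#'   [recovery_experiment()].
#' @examples
#' ds <- simulate_dataset(simulation_config(
#'   design_exp1(),
#'   groups = study_groups(strategy_spec("alternator")), seed = 1
#' ))
#' summarize_dyads(ds)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  design <- config$design
  n_total <- sum(vapply(config$groups, function(g) g$n_dyads, numeric(1)))
  id_width <- max(2L, nchar(as.character(n_total)))
  withr::with_seed(config$seed, {
    rows <- list()
    kinds <- character(0)
    dyad_no <- 0L
    for (g in config$groups) {
      for (d in seq_len(g$n_dyads)) {
        dyad_no <- dyad_no + 1L
        id <- sprintf(paste0("d%0", id_width, "d"), dyad_no)
        spec <- resolve_strategy(g$strategy)
        kinds[id] <- spec$kind
        rows[[length(rows) + 1]] <- simulate_dyad_trials(
          id, g, spec, design
        )
      }
    }
    trials <- dplyr::bind_rows(rows)
    ds <- dyad_dataset(design, trials)
    attr(ds, "strategy_kinds") <- kinds
    ds
  })
}

# A mixture dyad draws its component once, at creation.
resolve_strategy <- function(spec) {
  if (spec$kind != "mixture") return(spec)
  i <- sample.int(length(spec$components), 1, prob = spec$weights)
  spec$components[[i]]
}

simulate_dyad_trials <- function(id, group, spec, design) {
  n <- design$n_test_trials
  outcome <- tray <- large <- protest <- character(n)
  change <- logical(n)
  turn <- "A" # alternator state: who takes the large reward next
  for (t in seq_len(n)) {
    if (runif(1) < spec$p_no_agreement) {
      outcome[t] <- "no_agreement"
      tray[t] <- "none"
      large[t] <- "none"
      protest[t] <- "none"
      change[t] <- FALSE
      next
    }
    tray[t] <- if (runif(1) < spec$p_unequal) "unequal" else "equal"
    failed <- runif(1) < spec$p_coordination_failure
    outcome[t] <- if (failed) "unsuccessful_agreement" else "success"
    if (!failed && tray[t] == "unequal") {
      if (spec$kind == "alternator") {
        large[t] <- turn
        turn <- if (turn == "A") "B" else "A"
      } else {
        large[t] <- if (runif(1) < spec$p_dominant_large) "A" else "B"
      }
    } else {
      large[t] <- "none"
    }
    p_protest <- if (tray[t] == "unequal") {
      spec$protest_against_small
    } else {
      spec$protest_against_equal
    }
    protest[t] <- if (runif(1) < p_protest) {
      if (tray[t] == "unequal") "against_small" else "against_equal"
    } else {
      "none"
    }
    change[t] <- runif(1) < spec$p_change_of_tray
  }
  tibble::tibble(
    dyad_id = id, experiment = group$experiment, age_group = group$age_group,
    gender = group$gender, familiarity = group$familiarity,
    trial_index = seq_len(n), outcome = outcome, tray = tray,
    large_recipient = large, protest = protest, change_of_tray = change
  )
}
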