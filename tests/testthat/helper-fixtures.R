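# Trial-table builders for handcrafted dyads. `trays` uses the shorthand
# "E" (equal success), "A"/"B" (unequal success, large reward to A/B),
# "U" (unsuccessful agreement on the unequal tray), "e" (unsuccessful on
# the equal tray), "N" (no agreement).
make_dyad_trials <- function(id, trays, experiment = 1L, age_group = "5",
                             gender = "F", familiarity = "familiar",
                             protest = rep("none", length(trays)),
                             change = rep(FALSE, length(trays))) {
  outcome <- vapply(trays, function(x) switch(x,
    E = , A = , B = "success",
    U = , e = "unsuccessful_agreement",
    N = "no_agreement"
  ), character(1))
  tray <- vapply(trays, function(x) switch(x,
    E = , e = "equal", A = , B = , U = "unequal", N = "none"
  ), character(1))
  large <- vapply(trays, function(x) switch(x,
    A = "A", B = "B", "none"
  ), character(1))
  tibble::tibble(
    dyad_id = id, experiment = experiment, age_group = age_group,
    gender = gender, familiarity = familiarity,
    trial_index = seq_along(trays), outcome = outcome, tray = tray,
    large_recipient = large, protest = protest, change_of_tray = change
  )
}

make_dataset <- function(..., design = design_exp1()) {
  dyad_dataset(design, dplyr::bind_rows(...))
}

# A random-choice simulation config: 12 dyads x 4 trials, one age group,
# no failure processes — the chance-level reference population.
null_config <- function(seed, n_dyads = 12L, design = design_exp1()) {
  simulation_config(
    design,
    groups = list(list(
      experiment = 1L, age_group = "5", gender = "F",
      familiarity = "familiar", n_dyads = n_dyads,
      strategy = strategy_spec("random")
    )),
    seed = seed
  )
}
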