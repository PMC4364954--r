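#' Tray designs and analysis configuration
#'
#' A tray design describes the payoff structure of the two trays offered to
#' a dyad: the equal tray gives `E` rewards to each child, the unequal tray
#' gives `L` rewards to one child and `S` to the other (`L > S`), and every
#' dyad faces `n_test_trials` test trials.
#'
#' @param E Integer, rewards per child on the equal tray.
#' @param L Integer, large reward on the unequal tray.
#' @param S Integer, small reward on the unequal tray.
#' @param n_test_trials Integer, number of test trials per dyad.
#'
#' @return A `tray_design` object (a named list with fields `E`, `L`, `S`,
#'   `n_test_trials`).
#' @examples
#' tray_design(E = 2, L = 3, S = 1, n_test_trials = 4)
#' @export
tray_design <- function(E, L, S, n_test_trials = 4L) {
  check_count <- function(x, name, min = 0L) {
    if (length(x) != 1 || is.na(x) || !is.numeric(x) || x != as.integer(x) ||
        x < min) {
      abort(sprintf("`%s` must be a single integer >= %d.", name, min))
    }
    as.integer(x)
  }
  E <- check_count(E, "E")
  L <- check_count(L, "L")
  S <- check_count(S, "S")
  n_test_trials <- check_count(n_test_trials, "n_test_trials", min = 1L)
  if (L <= S) abort("`L` must exceed `S` (the unequal tray is unequal).")
  structure(
    list(E = E, L = L, S = S, n_test_trials = n_test_trials),
    class = "tray_design"
  )
}

#' @describeIn tray_design Design of the low-inequality game: (2,2) vs (3,1).
#' @export
design_exp1 <- function() tray_design(E = 2L, L = 3L, S = 1L, n_test_trials = 4L)

#' @describeIn tray_design Design of the high-inequality game: (2,2) vs (6,1).
#' @export
design_exp2 <- function() tray_design(E = 2L, L = 6L, S = 1L, n_test_trials = 4L)

#' @export
print.tray_design <- function(x, ...) {
  cat(sprintf(
    "<tray_design> equal (%d,%d) vs unequal (%d,%d), %d test trials\n",
    x$E, x$E, x$L, x$S, x$n_test_trials
  ))
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles the knobs shared by the stochastic analyses: the random seed,
#' the number of Monte Carlo repetitions, the classification threshold, and
#' the Monte Carlo p-value convention.
#'
#' @param seed Integer seed; mandatory for any stochastic operation.
#' @param n_reps Number of Monte Carlo repetitions (default 10000).
#' @param threshold Classification threshold, a fraction in (0.5, 1]
#'   (default 0.66, so that 2 of 3 successful trials qualifies).
#' @param p_convention `"plain"` (b/m, the proportion of null draws at least
#'   as extreme) or `"plus_one"` ((b+1)/(m+1), which cannot return 0).
#'
#' @return An `analysis_config` object.
#' @examples
#' analysis_config(seed = 1)
#' @export
analysis_config <- function(seed, n_reps = 10000L, threshold = 0.66,
                            p_convention = c("plain", "plus_one")) {
  if (missing(seed) || length(seed) != 1 || is.na(seed) ||
      seed != as.integer(seed)) {
    abort("`seed` must be supplied as a single integer.")
  }
  if (length(n_reps) != 1 || is.na(n_reps) || n_reps < 1 ||
      n_reps != as.integer(n_reps)) {
    abort("`n_reps` must be a single integer >= 1.")
  }
  if (length(threshold) != 1 || is.na(threshold) || threshold <= 0.5 ||
      threshold > 1) {
    abort("`threshold` must lie in (0.5, 1].")
  }
  p_convention <- match.arg(p_convention)
  structure(
    list(
      seed = as.integer(seed), n_reps = as.integer(n_reps),
      threshold = threshold, p_convention = p_convention
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf(
    "<analysis_config> seed %d, %d reps, threshold %.2f, %s p-values\n",
    x$seed, x$n_reps, x$threshold, x$p_convention
  ))
  invisible(x)
}

#' Read or write a design + analysis configuration JSON file
#'
#' The configuration document has two top-level keys: `design`
#' (`E`, `L`, `S`, `n_test_trials`) and `analysis` (`seed`, `n_reps`,
#' `threshold`, `p_convention`).
#'
#' @param path Path to a JSON file.
#' @return `read_config()` returns a list with elements `design`
#'   (a [tray_design()]) and `analysis` (an [analysis_config()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$design)) abort("Config is missing the `design` key.")
  if (is.null(raw$analysis)) abort("Config is missing the `analysis` key.")
  d <- raw$design
  a <- raw$analysis
  list(
    design = tray_design(
      E = d$E, L = d$L, S = d$S,
      n_test_trials = d$n_test_trials %||% 4L
    ),
    analysis = analysis_config(
      seed = a$seed,
      n_reps = a$n_reps %||% 10000L,
      threshold = a$threshold %||% 0.66,
      p_convention = a$p_convention %||% "plain"
    )
  )
}

#' @rdname read_config
#' @param design A [tray_design()].
#' @param analysis An [analysis_config()].
#' @export
write_config <- function(design, analysis, path) {
  jsonlite::write_json(
    list(
      design = unclass(design),
      analysis = unclass(analysis)
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
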