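#' Exact two-sided binomial test
#'
#' Computes the two-sided exact binomial p-value by tail doubling: twice
#' the smaller of the lower and upper tail probabilities of `k` under
#' Binomial(`n`, `p0`), capped at 1. Tail doubling reproduces the printed
#' small-sample first-choice p-values at `p0 = 0.5` and remains
#' well-defined for asymmetric nulls; the minimum-likelihood two-sided
#' method is deliberately not used.
#'
#' @param k Number of successes (0..n).
#' @param n Number of trials.
#' @param p0 Null success probability, strictly between 0 and 1.
#' @return An `exact_test` object: list with `method`, `statistic` (k),
#'   `n_effective` (n), `p_value`, `sidedness`.
#' @examples
#' binom_two_sided(2, 12) # p ~= 0.0386
#' binom_two_sided(6, 12) # p = 1
#' @export
binom_two_sided <- function(k, n, p0 = 0.5) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      k != round(k) || n != round(n) || k < 0 || n < 1 || k > n) {
    abort("`k` must be an integer in 0..n and `n` a positive integer.")
  }
  if (length(p0) != 1 || is.na(p0) || p0 <= 0 || p0 >= 1) {
    abort("`p0` must lie strictly between 0 and 1.")
  }
  lower <- stats::pbinom(k, n, p0)
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  structure(
    list(
      method = "binomial_two_sided", statistic = as.integer(k),
      n_effective = as.integer(n), ties_dropped = 0L, p_value = p,
      sidedness = "two_sided", degenerate = FALSE
    ),
    class = "exact_test"
  )
}

#' Exact Wilcoxon signed-rank test
#'
#' Exact signed-rank test on a vector of paired differences. Zero
#' differences are dropped before ranking and reported as ties; tied
#' nonzero magnitudes receive midranks. The null distribution of the
#' positive rank sum `T+` is exact — every one of the `2^m` equally likely
#' sign assignments of the `m` nonzero differences is accounted for — and
#' the two-sided p-value doubles the smaller tail (capped at 1).
#'
#' @param differences Numeric vector of signed differences (at least one).
#' @param sidedness `"two_sided"` (default) or `"one_sided_greater"`
#'   (`P(T+ >= t+)`).
#' @return An `exact_test` object with `statistic` (`T = min(T+, T-)`),
#'   `t_plus`, `n_effective` (nonzero differences), `ties_dropped`,
#'   `p_value`, `sidedness`, and `degenerate` (`TRUE` when every
#'   difference was zero, in which case `p_value = 1`).
#' @examples
#' wilcoxon_exact(c(1, 2, 3)) # T+ = 6, p = 0.25
#' @export
wilcoxon_exact <- function(differences,
                           sidedness = c("two_sided", "one_sided_greater")) {
  sidedness <- match.arg(sidedness)
  if (length(differences) < 1 || anyNA(differences)) {
    abort("`differences` must be a non-empty numeric vector without NAs.")
  }
  nonzero <- differences[differences != 0]
  m <- length(nonzero)
  ties_dropped <- length(differences) - m
  if (m == 0) {
    return(structure(
      list(
        method = "wilcoxon_exact", statistic = 0, t_plus = 0,
        n_effective = 0L, ties_dropped = as.integer(ties_dropped),
        p_value = 1, sidedness = sidedness, degenerate = TRUE
      ),
      class = "exact_test"
    ))
  }
  if (m > 20) {
    abort("Exact enumeration supported for at most 20 nonzero differences.")
  }
  ranks <- rank(abs(nonzero))
  t_plus <- sum(ranks[nonzero > 0])
  t_minus <- sum(ranks) - t_plus

  # Exact distribution of T+ over all 2^m sign assignments. Midranks can be
  # half-integers, so the convolution runs on doubled ranks, which are
  # integers; probabilities stay exact up to binary floating point.
  r2 <- as.integer(round(2 * ranks))
  probs <- signrank_distribution(r2)
  t2 <- as.integer(round(2 * t_plus))
  p_lower <- sum(probs[seq_len(t2 + 1L)])
  p_upper <- sum(probs[(t2 + 1L):length(probs)])
  p <- switch(sidedness,
    two_sided = min(1, 2 * min(p_lower, p_upper)),
    one_sided_greater = p_upper
  )
  structure(
    list(
      method = "wilcoxon_exact", statistic = min(t_plus, t_minus),
      t_plus = t_plus, n_effective = as.integer(m),
      ties_dropped = as.integer(ties_dropped), p_value = p,
      sidedness = sidedness, degenerate = FALSE
    ),
    class = "exact_test"
  )
}

# Probability mass of 2*T+ on 0..sum(r2), by iterated convolution over the
# doubled ranks; each rank enters the positive sum with probability 1/2.
signrank_distribution <- function(r2) {
  total <- sum(r2)
  mass <- numeric(total + 1L)
  mass[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), mass[seq_len(total + 1L - r)])
    mass <- (mass + shifted) / 2
  }
  mass
}

#' @export
print.exact_test <- function(x, ...) {
  cat(sprintf("<exact_test> %s (%s)\n", x$method, x$sidedness))
  if (x$method == "wilcoxon_exact") {
    cat(sprintf("  T = %g (T+ = %g), n = %d, ties dropped = %d\n",
                x$statistic, x$t_plus, x$n_effective, x$ties_dropped))
  } else {
    cat(sprintf("  k = %g, n = %d\n", x$statistic, x$n_effective))
  }
  cat(sprintf("  p = %.4g%s\n", x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate: all differences zero)"
              else ""))
  invisible(x)
}

#' Expected absolute reward difference under random role assignment
#'
#' If a dyad obtains the unequal tray `k` times and the large-reward role
#' is assigned at random each time, the signed reward difference performs a
#' symmetric random walk with steps of size `delta = L - S`. This function
#' returns the mean absolute endpoint over all `2^k` equally likely role
#' sequences — the chance-level expectation the observed absolute
#' difference is tested against. Equal-tray trials shift both children
#' equally and contribute nothing.
#'
#' Computed by the closed form
#' `delta * k * choose(k - 1, floor((k - 1) / 2)) / 2^(k - 1)` for
#' `k >= 1` (0 for `k = 0`), which equals the full `2^k` enumeration mean
#' exactly.
#'
#' @param k_unequal Number of unequal-tray successes (vectorised).
#' @param delta Reward difference `L - S` on the unequal tray.
#' @return Expected absolute difference(s), non-negative numeric.
#' @examples
#' expected_abs_diff(2, 2) # (4 + 4 + 0 + 0) / 4 = 2
#' expected_abs_diff(4, 2) # 3
#' @export
expected_abs_diff <- function(k_unequal, delta) {
  if (anyNA(k_unequal) || any(k_unequal < 0) ||
      any(k_unequal != round(k_unequal))) {
    abort("`k_unequal` must be non-negative integer(s).")
  }
  if (length(delta) != 1 || is.na(delta) || delta < 0) {
    abort("`delta` must be a single non-negative number.")
  }
  out <- numeric(length(k_unequal))
  pos <- k_unequal >= 1
  k <- k_unequal[pos]
  out[pos] <- delta * k * choose(k - 1, floor((k - 1) / 2)) / 2^(k - 1)
  out
}

#' Observed vs expected inequality across dyads
#'
#' For every dyad with at least one successful trial, pairs the observed
#' absolute reward difference with its chance-level expectation
#' [expected_abs_diff()] given how often that dyad took the unequal tray,
#' then tests the per-dyad (observed - expected) differences with
#' [wilcoxon_exact()]. A significantly positive shift means dyads ended up
#' more unequal than random large-role assignment would produce (e.g. one
#' child monopolising the large plate); a negative shift means more equal
#' (e.g. turn taking).
#'
#' @param dataset A [dyad_dataset()].
#' @param sidedness Passed to [wilcoxon_exact()].
#' @return A list of class `obs_vs_exp_test`: `test` (the `exact_test`),
#'   `table` (per-dyad tibble with `observed`, `expected`, `difference`),
#'   `n_dyads_included`, `n_dyads_excluded`.
#' @export
observed_vs_expected_test <- function(dataset,
                                      sidedness = c("two_sided",
                                                    "one_sided_greater")) {
  sidedness <- match.arg(sidedness)
  sm <- summarize_dyads(dataset)
  eligible <- sm[sm$n_success >= 1, ]
  if (nrow(eligible) == 0) {
    abort("No dyad has a successful trial; the test is undefined.")
  }
  delta <- dataset$design$L - dataset$design$S
  tab <- tibble::tibble(
    dyad_id = eligible$dyad_id,
    n_unequal = eligible$n_unequal,
    observed = eligible$abs_diff,
    expected = expected_abs_diff(eligible$n_unequal, delta)
  )
  tab$difference <- tab$observed - tab$expected
  structure(
    list(
      test = wilcoxon_exact(tab$difference, sidedness = sidedness),
      table = tab,
      n_dyads_included = nrow(eligible),
      n_dyads_excluded = nrow(sm) - nrow(eligible)
    ),
    class = "obs_vs_exp_test"
  )
}

#' @export
print.obs_vs_exp_test <- function(x, ...) {
  cat(sprintf(
    "<obs_vs_exp_test> %d dyads (%d excluded, no successful trial)\n",
    x$n_dyads_included, x$n_dyads_excluded
  ))
  print(x$test)
  invisible(x)
}
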