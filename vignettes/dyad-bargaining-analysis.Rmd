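---
title: "Analysing dyadic tray-choice bargaining data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing dyadic tray-choice bargaining data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadbargain)
```

## The experimental setting

Two children sit in front of two pulling apparatuses. One tray holds an
equal split — `E` rewards on each plate — and the other an unequal split
— `L` rewards on one plate, `S` on the other, with `L > S`. The board
moves only if both children pull together, so every trial is a
face-to-face negotiation: the pair must agree on one tray before anyone
gets anything, and each child keeps whatever their own plate held. A trial
can end three ways: the pair never agrees (*no agreement*), they agree but
fail to coordinate the pull (*unsuccessful agreement*), or they retrieve a
tray (*success*). On a successful unequal-tray trial one child — the
*large recipient* — gets `L` and the partner gets `S`.

The package ships the two designs used in the study this machinery was
built for: `design_exp1()` is (2, 2) vs (3, 1) and `design_exp2()` is
(2, 2) vs (6, 1), both with 4 test trials per dyad. All analysis code is
parameterised by `tray_design(E, L, S, n_test_trials)`, so other payoff
structures work unchanged.

The dyad, not the child, is the unit of analysis throughout: every
proportion is computed within a dyad first and only then averaged or
tested across dyads.

## The data model

A `dyad_dataset()` couples a design with one row per trial. Validation is
total: every malformed record produces an error naming the row and field,
and the two structural rules — `tray == "none"` exactly on no-agreement
trials, a large recipient exactly on successful unequal trials — are
enforced on construction, on file input, and on simulator output alike.
`read_trials()` / `write_trials()` round-trip a fixed CSV schema
byte-exactly, which keeps fixtures diffable and makes "same analysis, same
bytes" a testable property.

Child identity within a dyad is positional: the two children are "A" and
"B" as assigned at data entry. Every statistic in the package is symmetric
in A/B; only the large-recipient bookkeeping distinguishes them.
Unsuccessful agreements retain their agreed tray and count toward
agreement rates, but never enter reward or choice-proportion denominators
— a dyad that never succeeded has *undefined* (not zero) choice
proportions, and such dyads are excluded from choice-based analyses and
reported in `n_excluded` and the report's warning list.

Denominators differ by measure, deliberately:

* tray-choice proportions (`prop_unequal`, `prop_equal`) use successful
  trials;
* protest proportions use all trials, because protests are coded from the
  moment the pair enters the room, whatever the outcome becomes;
* change-of-tray proportions use successful trials, because an outcome
  can only be attributed to a change where there is an outcome.

Whether no-agreement trials belong in the protest denominator is a
convention, not a fact about the data; the choice here (include them) is
flagged in the analysis report's warnings so downstream users see it.

## The two Monte Carlo strategy tests

The central question — do dyads *choose* between the trays, rather than
drift at random? — is answered against a simulated chance baseline rather
than a textbook null, because each dyad contributes a different number of
successful trials.

For each of `n_reps` repetitions, every dyad is replaced by a fair coin
flipped once per successful trial it actually had; the statistic of
interest is recomputed; and the p-value is the proportion of repetitions
whose statistic lies *at least as far* from its chance expectation as the
observed one (a non-strict comparison, so a repetition that exactly ties
the observed value counts).

* **Pure strategies** (`pure_strategy_test()`): the statistic is the mean
  across dyads of |proportion unequal − 0.5|. It is large when dyads are
  individually consistent, whichever tray each prefers.
* **Common strategy** (`common_strategy_test()`): the statistic is the
  mean proportion of unequal choices, and extremeness is two-sided
  distance from 0.5. It is large only when dyads lean the same way.

The pair dissociates by construction: a population in which half the
dyads always take the unequal tray and half always the equal tray has
maximal pure-strategy signal and no common-strategy signal at all. The
test suite pins this qualitative dissociation down as a property.

Two p-value conventions are exposed. `"plain"` is `b/m`, the literal
proportion of qualifying repetitions, and can return exactly 0;
`"plus_one"` is `(b+1)/(m+1)`, which cannot. `"plain"` is the default
because it is the straightforward reading of "proportion of simulations";
the alternative is provided because a reported Monte Carlo p-value of
0.0001 at 10,000 repetitions is ambiguous between the two.

### Discreteness and calibration

With 12 dyads of at most 4 successful trials, both statistics live on a
coarse grid, and a distance-based Monte Carlo p-value on a discrete
statistic is necessarily conservative: the attainable type-I error is the
largest null tail probability not exceeding the nominal level. Convolving
the exact per-dyad null distributions shows that at a nominal 5% level
the attainable level is about 2.6% for the pure-strategy statistic and
2.9% for the common-strategy statistic at the 12-dyads-by-4-trials scale.
Calibration experiments on this package (`calibration_experiment()`, and
the test suite's exact-level check) should therefore be read against
those attainable levels, not against 5% itself: rejection rates near
0.026–0.030 under a true null are the correct behaviour of a valid,
conservative test, not evidence of miscalibration. The suite asserts both
that the empirical rate matches the exact attainable level and that the
tests are never anti-conservative.

The test suite and the acceptance script run the calibration at 500
replicate datasets with 2,000 Monte Carlo repetitions per test — the
package's chosen compromise between the Monte Carlo standard error of a
rejection rate (about 0.7 percentage points at a 2.6% rate) and runtime.
Headline analyses default to `n_reps = 10000`.

## Expected inequality under random role assignment

If a dyad took the unequal tray `k` times and the large role had been
assigned by coin flip each time, the signed reward difference between the
children is a symmetric random walk with step `delta = L − S`. The
chance-level expected absolute difference is the mean of |endpoint| over
all `2^k` role sequences. `expected_abs_diff()` evaluates this with the
closed form

```
E|D_k| = delta * k * C(k-1, floor((k-1)/2)) / 2^(k-1),   k >= 1
```

which the test suite verifies against a brute-force enumeration of all
`2^k` sequences for `k` up to 12 and both `delta = 2` and `delta = 5`
before anything relies on it. Equal-tray trials move both children
equally and drop out of the difference.

`observed_vs_expected_test()` pairs each dyad's observed absolute
difference with this expectation at its own `k` and feeds the per-dyad
differences to the exact Wilcoxon signed-rank test: a positive shift
means more inequality than chance (monopolised large roles), a negative
shift more equality (turn taking).

## Exact small-sample tests

`binom_two_sided()` doubles the smaller binomial tail and caps at 1. Tail
doubling is used instead of the minimum-likelihood method because it is
well-defined for asymmetric nulls and reproduces the conventional printed
values at `p0 = 0.5`; the two methods coincide there anyway.

`wilcoxon_exact()` follows the standard exact conventions: zero
differences are dropped before ranking and reported as `ties_dropped`;
tied magnitudes get midranks; the null distribution of the positive rank
sum `T+` is exact over all `2^m` sign assignments; the two-sided p
doubles the smaller of `P(T+ <= t)` and `P(T+ >= t)`, capped at 1.
Internally the distribution is built by convolution over doubled ranks
(doubling makes midranks integral), which is algebraically identical to
the full enumeration; the suite checks it against an independent
enumeration oracle on 500 random inputs and against `stats::wilcox.test`
on tie-free cases. Enumeration is refused beyond `m = 20` nonzero
differences — the intended use is per-dyad analyses with `m <= 15`, and
an exact method silently degrading to an approximation would be worse
than an error. A one-sided variant (`one_sided_greater`) is available
because reported signed-rank results on this kind of data do not always
state sidedness.

## Theoretical outcome curves

Plotting each dyad's highest-earner reward share against its
unequal-choice proportion needs two reference curves. With `u` unequal
successes out of `n`, total rewards are `u(L+S) + (n−u)2E` and:

* **monopoly** — one child takes every large role:
  `(uL + (n−u)E) / (u(L+S) + (n−u)2E)`;
* **alternation** — the large role alternates:
  `(ceil(u/2)L + floor(u/2)S + (n−u)E) / (u(L+S) + (n−u)2E)`.

Both equal 0.5 at `u = 0`; monopoly rises monotonically to `L/(L+S)`
(0.75 and 6/7 for the two shipped designs); alternation returns to 0.5 at
every even `u` and stays weakly below monopoly everywhere, with equality
only at `u <= 1`. Real dyads fall between the curves.
`highest_earner_points()` emits the empirical points and `curve_table()`
the curves; plotting is left to the caller.

## Dyad pattern classification

`classify_dyads()` assigns each dyad one label from its successful
trials, evaluating in order:

1. **equality** — equal-tray share of successes `>= tau`;
2. **reciprocal** — at least 2 unequal successes and equal large-role
   counts for the two children;
3. **inequality** — one child's large-role share of successes `>= tau`;
4. **mixed** — none of the above;

with **undetermined** reserved for dyads with no successful trial. The
threshold `tau = 0.66` is compared with `>=` so that 2 of 3 successful
trials qualifies as a majority — the natural reading when dyads sometimes
succeed only 3 times out of 4. The precedence order is a design choice the
labels themselves do not force: the categories can collide only in
degenerate corners, and putting equality and reciprocity — the two "fair"
patterns — ahead of inequality resolves those corners in favour of the
more specific description of what the dyad did. Requiring two unequal
successes for *reciprocal* stops a single unequal trial (whose large-role
counts are trivially 1–0, never equal) from being misread; note a lone
unequal success among several equal ones classifies by the remaining
rules. Both conventions are stated here rather than buried in code, and
the classification threshold travels in `analysis_config()` so a report
records what was used.

## The synthetic-data generator

No trial-level data accompany the study, so `simulate_dataset()` exists
to make every stage testable and to run calibration and recovery
experiments. It emulates the structure the analysis assumes: groups of
dyads with fixed covariates (the study shape — 12 same-sex dyads per age
group, balanced familiarity — is one helper call, `study_groups()`), and
per-trial generative behaviour in the order the task unfolds: no
agreement, tray choice, coordination failure, large-role assignment,
protest, change-of-tray. Strategy kinds (`random`, `monopolist`,
`equal_preferrer`, `alternator`, `mixture`) preset the choice parameters;
failure and protest rates default to zero and are set explicitly where an
experiment needs them.

Deliberate simplifications, and what they imply for the tests:

* the alternator's turn state advances only on successful unequal trials
  — failed trials do not consume a turn — and resets per dyad;
* protests and changes of tray are drawn independently given the agreed
  tray's context, so the generator reproduces context-specific *rates*
  (protests mostly against the small amount) but not joint structure such
  as protests causing changes;
* there is no learning across trials and no dependence between trials
  beyond the alternator's turn; real dyads plainly negotiate across
  trials ("you got the big one last time").

Passing calibration and recovery tests on this generator therefore shows
the statistics behave correctly under the stated chance model — it cannot
show anything about serial dependence or protest-outcome coupling in real
data, which the generator does not produce.

Mixture dyads draw their component once, at dyad creation: a mixture
models a heterogeneous *population*, not a dyad that switches policy
mid-session.

## Reproducibility and numerics

Every stochastic entry point takes an explicit seed and restores the
caller's RNG state (`withr::with_seed`), so a dataset, a test result or a
whole report is a pure function of its inputs. Replicate experiments draw
per-replicate seeds from the master seed. Exact distributions are built
in double precision from dyadic rationals (probabilities with
power-of-two denominators), so enumeration comparisons in the tests can
afford tolerances near machine epsilon. Degenerate inputs have defined
behaviour rather than incidental behaviour: all-zero difference vectors
give `p = 1` with a `degenerate` flag, zero-success dyads are excluded
and counted everywhere, and an empty eligible set is an error, not a NaN.

## Known limitations

* Covariate modelling (age, gender, familiarity effects via regression)
  is out of scope; the package stops at grouped descriptives and the
  bespoke tests.
* The exact Wilcoxon is restricted to `m <= 20` nonzero differences by
  design; there is no normal-approximation fallback.
* The generator's independence assumptions above mean power estimates
  against serially dependent strategies are not available.
* Group summary SDs use the sample (n−1) convention; with 12 dyads per
  group the distinction from the population convention is material when
  comparing against published means and SDs.
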