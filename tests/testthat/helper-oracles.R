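# Independent oracles used to check the exact machinery. These deliberately
# re-derive each quantity by brute force and share no code with R/.

# Mean |endpoint| of a +/-delta random walk over all 2^k sign sequences.
oracle_expected_abs_diff <- function(k, delta) {
  if (k == 0) return(0)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  mean(abs(rowSums(signs * delta)))
}

# Exact Wilcoxon signed-rank p by enumerating all 2^m sign assignments of
# the nonzero differences (midranks for tied magnitudes).
oracle_wilcoxon <- function(differences,
                            sidedness = c("two_sided", "one_sided_greater")) {
  sidedness <- match.arg(sidedness)
  d <- differences[differences != 0]
  m <- length(d)
  if (m == 0) return(list(t_plus = 0, p = 1))
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  t_all <- as.vector(signs %*% r)
  eps <- 1e-9
  p_lo <- mean(t_all <= t_obs + eps)
  p_hi <- mean(t_all >= t_obs - eps)
  p <- if (sidedness == "two_sided") min(1, 2 * min(p_lo, p_hi)) else p_hi
  list(t_plus = t_obs, p = p)
}

# Exact rejection probability at level alpha of a Monte Carlo test whose
# statistic under the null is sum(Y_i)/denominator with iid integer-valued
# Y_i; `pmf` is the per-dyad pmf on 0:(length(pmf)-1). Used to know the
# attainable type-I error of the discrete strategy tests independently of
# the implementation.
oracle_discrete_rejection <- function(pmf, n_dyads, alpha) {
  dist <- 1
  for (i in seq_len(n_dyads)) {
    nd <- numeric(length(dist) + length(pmf) - 1)
    for (j in seq_along(pmf)) {
      idx <- seq_along(dist) + j - 1
      nd[idx] <- nd[idx] + dist * pmf[j]
    }
    dist <- nd
  }
  tail_p <- rev(cumsum(rev(dist))) # P(sum >= s), s = 0, 1, ...
  sum(dist[tail_p <= alpha])
}
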