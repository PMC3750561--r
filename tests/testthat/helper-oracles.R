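# Independent oracles, deliberately brute-force and separate from the
# implementation paths they validate.

# pairwise member/non-member concordance count (AUC oracle)
oracle_concordance_auc <- function(member_pos, n) {
  nonmember <- setdiff(seq_len(n), member_pos)
  conc <- 0L
  for (i in member_pos)
    for (j in nonmember)
      if (i < j) conc <- conc + 1L
  conc / (length(member_pos) * length(nonmember))
}

# exact two-sided Mann-Whitney p by enumerating all rank splits
oracle_wilcoxon_p <- function(xa, xb) {
  n <- length(xa) + length(xb)
  pooled <- c(xa, xb)
  r <- rank(pooled)
  u_obs <- sum(r[seq_along(xa)]) - length(xa) * (length(xa) + 1) / 2
  splits <- utils::combn(n, length(xa))
  u_all <- apply(splits, 2, function(idx)
    sum(r[idx]) - length(xa) * (length(xa) + 1) / 2)
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# two-sided Fisher p: sum of hypergeometric table probabilities at most as
# likely as the observed table (with the conventional 1 + 1e-7 float guard)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand-rolled two-group log-rank chi-square (Mantel-Cox), no censoring ties
# with events handled the standard way
oracle_logrank_chisq <- function(time_a, event_a, time_b, event_b) {
  times <- sort(unique(c(time_a[event_a], time_b[event_b])))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    na <- sum(time_a >= t); nb <- sum(time_b >= t); n <- na + nb
    da <- sum(time_a == t & event_a); db <- sum(time_b == t & event_b)
    d <- da + db
    if (n <= 1 || d == 0) next
    o_minus_e <- o_minus_e + (da - d * na / n)
    v <- v + d * (na / n) * (nb / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# tiny deterministic ranked list over letters for AUC unit tests
ranked_letters <- function(n) LETTERS[seq_len(n)]
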