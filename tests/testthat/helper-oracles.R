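# Independent oracles: brute-force / closed-form re-derivations of every
# statistic, coded against textbook formulas and kept free of the package's
# own implementation paths.

# textbook paired t on differences b - a, two-sided
oracle_paired_t <- function(a, b) {
  d <- b - a
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# chi-square survival function at even df = 2k, closed form
# P(X > x) = exp(-x/2) * sum_{i=0}^{k-1} (x/2)^i / i!
oracle_chisq_surv_even <- function(x, k)
  exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))

# Fisher's method by the closed form above
oracle_fisher <- function(ps) {
  x <- -2 * sum(log(ps))
  oracle_chisq_surv_even(x, length(ps))
}

# full DCI score from raw replicate arrays, composed of the two oracles
oracle_dci <- function(controls, treatments) {
  ts <- c(); ps <- c()
  for (a in controls) for (b in treatments) {
    r <- oracle_paired_t(a, b)
    ts <- c(ts, r$t); ps <- c(ps, r$p)
  }
  p <- oracle_fisher(ps)
  sgn <- sign(sum(ts))
  list(S = sgn * -log10(p), p = p, sign = sgn)
}

# AUROC by exhaustive concordant-pair counting with half-credit for ties
oracle_auroc <- function(score, bound) {
  sb <- score[bound]; su <- score[!bound]
  cmp <- outer(sb, su, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(sb) * length(su))
}

# exact rank-sum test by complete enumeration of group assignments
oracle_ranksum_exact <- function(x, y, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  sets <- combn(length(pooled), n1)
  stats <- apply(sets, 2, function(idx) sum(r[idx]))
  if (alternative == "greater") return(mean(stats >= obs))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu))
}

# Monte-Carlo Irwin-Hall CDF
oracle_irwin_hall_mc <- function(s, k, n = 1e6) {
  sums <- colSums(matrix(runif(k * n), k))
  est <- mean(sums <= s)
  se <- sqrt(est * (1 - est) / n)
  list(p = est, se = se)
}
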