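# Independent brute-force oracles used to check the statistical routines.
# These stay deliberately naive: full enumeration or direct formula
# evaluation, never calls into the code paths they verify.

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled ranks to group A (values must be tie-free).
oracle_wilcoxon_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # U statistic for A
  idx <- utils::combn(n + m, n)
  w_all <- apply(idx, 2, function(ii) sum(r[ii])) - n * (n + 1) / 2
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Kruskal-Wallis H from first principles: rank formula with tie correction.
oracle_kruskal_h <- function(values, groups) {
  groups <- as.factor(groups)
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) -
    3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins (probability-mass definition, as fisher.test).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - m2):min(c1, m1)
  pr <- stats::dhyper(support, m1, m2, c1)
  p_obs <- stats::dhyper(a, m1, m2, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by direct definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Total variation distance between the empirical distribution of counts
# and the NB(mu, kon) pmf (tail mass beyond the observed support included).
tv_vs_nb <- function(x, mu, kon) {
  hi <- max(x, stats::qnbinom(1 - 1e-9, size = kon, mu = mu))
  emp <- tabulate(x + 1, nbins = hi + 1) / length(x)
  pmf <- stats::dnbinom(0:hi, size = kon, mu = mu)
  0.5 * (sum(abs(emp - pmf)) + (1 - sum(pmf)))
}
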