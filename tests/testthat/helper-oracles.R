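# Independent oracles used to cross-check package computations. These are
# deliberately written along different routes than the implementation.

# Two-sided Fisher exact p by brute-force enumeration over the hypergeometric
# support, computing each table's probability from the factorial formula
# P = r1! r2! c1! c2! / (N! a! b! c! d!).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  lmarg <- lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
    lfactorial(n)
  tab_prob <- function(x) {
    exp(lmarg - lfactorial(x) - lfactorial(r1 - x) - lfactorial(c1 - x) -
          lfactorial(r2 - c1 + x))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, tab_prob, numeric(1))
  p_obs <- tab_prob(a)
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

# Step-up FDR adjustment written out by hand (sorted p, q_i = min_{j>=i}
# p_j * m / j, clamped, returned in input order).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(m)
  out[o] <- pmin(q_sorted, 1)
  out
}

# Cohort data frame matching a fixed 2x2 of factor x outcome counts.
cohort_from_counts <- function(a, b, c, d, factor_col = "f",
                               outcome_col = "o") {
  out <- data.frame(
    f = c(rep(1, a + b), rep(0, c + d)),
    o = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  )
  names(out) <- c(factor_col, outcome_col)
  out
}
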