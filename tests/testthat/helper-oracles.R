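# Independent brute-force oracles for the exact tests. These are
# deliberately naive (combinatorial sums and full enumeration) and share
# no code with the implementation they check.

# Upper-tail hypergeometric by direct combinatorial summation.
hyper_tail_bf <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  j <- k:hi
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Upper-tail binomial by direct summation.
binom_tail_bf <- function(k, n, p0) {
  if (k > n) return(0)
  j <- k:n
  sum(choose(n, j) * p0^j * (1 - p0)^(n - j))
}

# All 2 x k tables with the margins of `tab`, with their conditional
# probabilities; two-sided p sums probabilities <= the observed table's.
fisher_2xk_bf <- function(tab) {
  cs <- colSums(tab)
  r1 <- sum(tab[1, ])
  total <- sum(tab)
  prob_of <- function(a) prod(choose(cs, a)) / choose(total, r1)
  enum <- function(j, left) {
    if (j == length(cs)) {
      if (left <= cs[j]) return(matrix(left, 1, 1))
      return(NULL)
    }
    out <- NULL
    for (a in 0:min(cs[j], left)) {
      rest <- enum(j + 1, left - a)
      if (!is.null(rest)) out <- rbind(out, cbind(a, rest))
    }
    out
  }
  tops <- enum(1, r1)
  probs <- apply(tops, 1, prob_of)
  p_obs <- prob_of(tab[1, ])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
# of the pooled sample (no ties).
mw_bf <- function(x, y) {
  m <- length(x)
  n <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">"))
  }
  u_obs <- u_of(seq_len(m))
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, u_of)
  lo <- min(u_obs, m * n - u_obs)
  hi <- max(u_obs, m * n - u_obs)
  mean(us <= lo | us >= hi)
}
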