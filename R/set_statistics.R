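# Overlap and distribution tests used throughout the analysis. All
# enrichment tests are upper-tail by default; extreme tails are computed in
# log space by the underlying distribution functions, so p-values far below
# 1e-300 on the log scale remain meaningful even when the linear-space
# value underflows to the smallest representable double.

#' Upper-tail hypergeometric overlap test
#'
#' Probability of drawing at least `k` members of a `K`-element category in
#' a sample of `n` from a universe of `N`, the enrichment test used for all
#' gene-set overlaps.
#'
#' @param N universe size.
#' @param K size of the first set (category).
#' @param n size of the second set (sample).
#' @param k observed overlap.
#' @param log_p return the natural-log p-value instead.
#' @return `P(X >= k)` (or its natural log).
#' @export
hypergeometric_overlap <- function(N, K, n, k, log_p = FALSE) {
  stopifnot(N >= 0, K >= 0, n >= 0, K <= N, n <= N)
  if (k > min(K, n) || k < max(0, K + n - N)) {
    stop(sprintf("infeasible overlap k=%d for N=%d, K=%d, n=%d", k, N, K, n))
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = log_p)
}

#' Overlap test between two gene sets
#'
#' Convenience wrapper computing the overlap of two identifier sets within a
#' universe and its upper-tail hypergeometric p-value.
#'
#' @param universe character vector of all identifiers.
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @return One-row data frame with `universe_n`, `set_a_n`, `set_b_n`,
#'   `overlap_n`, `p`, `test`.
#' @export
overlap_test <- function(universe, set_a, set_b) {
  universe <- unique(universe)
  set_a <- unique(set_a[set_a %in% universe])
  set_b <- unique(set_b[set_b %in% universe])
  k <- length(intersect(set_a, set_b))
  data.frame(universe_n = length(universe), set_a_n = length(set_a),
             set_b_n = length(set_b), overlap_n = k,
             p = hypergeometric_overlap(length(universe), length(set_a),
                                        length(set_b), k),
             test = "hypergeometric", stringsAsFactors = FALSE)
}

#' Fisher's exact test for a 2 x k table
#'
#' Exact conditional test with fixed margins; the two-sided p-value sums the
#' probabilities of all tables no more probable than the observed one.
#' Degenerate tables (fewer than two informative rows or columns) return
#' p = 1.
#'
#' @param table 2 x k matrix of non-negative integer counts, k in 2..4.
#' @return Two-sided p-value.
#' @export
fisher_exact_2xk <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2, ncol(table) >= 1, all(table >= 0))
  keep <- colSums(table) > 0
  table <- table[, keep, drop = FALSE]
  if (ncol(table) < 2 || any(rowSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by enumeration of rankings when `m + n <= 16` and there
#' are no ties, tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric samples.
#' @return List with `U` (number of (x, y) pairs with x > y, ties counting
#'   one half) and `p`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 16) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' One-sided (upper-tail) binomial test
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability.
#' @param log_p return the natural-log p-value instead.
#' @return `P(X >= k)` under Binomial(`n`, `p0`).
#' @export
binomial_onesided <- function(k, n, p0, log_p = FALSE) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = log_p)
}

#' Multiple-testing adjustment
#'
#' Step-up Benjamini-Hochberg FDR (default) or the step-down Hochberg
#' family-wise procedure.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"hochberg"`.
#' @return Adjusted values in `[0, 1]`, monotone in p-value rank.
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "hochberg")) {
  method <- match.arg(method)
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = method)
}

#' Upper-tail chi-squared probability
#'
#' Shared tail routine for the Pearson chi-squared tests in the package.
#'
#' @param stat chi-squared statistic.
#' @param df degrees of freedom.
#' @return `P(X >= stat)` for a chi-squared distribution with `df` degrees
#'   of freedom.
#' @export
chisq_pvalue <- function(stat, df) {
  stopifnot(stat >= 0, df >= 1)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}
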