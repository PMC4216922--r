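# CpG promoter classing from sequence alone: promoters are scored by the
# maximum CpG observed/expected ratio and GC content over sliding windows
# and assigned to high (HCP), intermediate/weak (ICP), or low (LCP) CpG
# classes.

seq_to_chars <- function(seq) {
  if (inherits(seq, "XString") || inherits(seq, "XStringSet")) {
    seq <- as.character(seq)
  }
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

#' CpG observed/expected ratio
#'
#' `(#CpG * L) / (#C * #G)` where `L` counts the non-N bases; 0 when the
#' sequence contains no C or no G.
#'
#' @param seq DNA sequence (character scalar or `DNAString`), alphabet
#'   ACGTN; N is excluded from all counts.
#' @return The observed/expected ratio.
#' @export
cpg_observed_expected <- function(seq) {
  ch <- seq_to_chars(seq)
  if (length(ch) < 2) stop("sequence must have length >= 2")
  nC <- sum(ch == "C")
  nG <- sum(ch == "G")
  if (nC == 0 || nG == 0) return(0)
  n <- length(ch)
  cpg <- sum(ch[-n] == "C" & ch[-1] == "G")
  L <- sum(ch %in% c("A", "C", "G", "T"))
  cpg * L / (nC * nG)
}

#' GC content
#'
#' @inheritParams cpg_observed_expected
#' @return `(#G + #C) / (#A + #C + #G + #T)`.
#' @export
gc_content <- function(seq) {
  ch <- seq_to_chars(seq)
  if (!length(ch)) stop("empty sequence")
  acgt <- sum(ch %in% c("A", "C", "G", "T"))
  if (acgt == 0) stop("sequence contains no ACGT bases")
  sum(ch %in% c("G", "C")) / acgt
}

# Sliding-window o/e and GC for one character vector; cumulative sums keep
# the scan linear in sequence length.
window_cpg_stats <- function(ch, window, step) {
  n <- length(ch)
  isC <- ch == "C"
  isG <- ch == "G"
  isACGT <- ch %in% c("A", "C", "G", "T")
  isCpG <- c(isC[-n] & isG[-1], FALSE)
  cumC <- c(0, cumsum(isC))
  cumG <- c(0, cumsum(isG))
  cumN <- c(0, cumsum(isACGT))
  cumCpG <- c(0, cumsum(isCpG))
  starts <- seq.int(1L, n - window + 1L, by = step)
  ends <- starts + window - 1L
  wC <- cumC[ends + 1L] - cumC[starts]
  wG <- cumG[ends + 1L] - cumG[starts]
  wL <- cumN[ends + 1L] - cumN[starts]
  # dinucleotides fully inside the window: positions start .. end-1
  wCpG <- cumCpG[ends] - cumCpG[starts]
  oe <- ifelse(wC > 0 & wG > 0, wCpG * wL / (wC * wG), 0)
  gc <- ifelse(wL > 0, (wC + wG) / wL, 0)
  data.frame(start = starts, oe = oe, gc = gc)
}

#' Classify a promoter sequence by CpG content
#'
#' Sliding-window scheme: a promoter is HCP if any window reaches both the
#' o/e and GC thresholds, LCP if no window reaches the lower o/e threshold,
#' and ICP otherwise. Classification is case-insensitive and deterministic.
#'
#' @param seq promoter sequence (conventionally 1 kb, -700..+300 of the
#'   TSS).
#' @param window sliding-window width in bp.
#' @param step window step in bp.
#' @param hcp_oe,hcp_gc o/e and GC thresholds a window must jointly reach
#'   for the HCP call.
#' @param lcp_oe o/e threshold below which (in every window) a promoter is
#'   LCP.
#' @return List with `cpg_class` (`"HCP"`, `"ICP"` or `"LCP"`), `best_oe`
#'   (maximum window o/e) and `best_gc_at_oe` (GC of that window).
#' @export
classify_promoter <- function(seq, window = 500L, step = 5L,
                              hcp_oe = 0.75, hcp_gc = 0.55, lcp_oe = 0.48) {
  ch <- seq_to_chars(seq)
  if (length(ch) < window) {
    stop(sprintf("sequence (%d bp) shorter than window (%d bp)",
                 length(ch), window))
  }
  w <- window_cpg_stats(ch, window, step)
  best <- which.max(w$oe)
  cls <- if (any(w$oe >= hcp_oe & w$gc >= hcp_gc)) "HCP"
         else if (all(w$oe < lcp_oe)) "LCP"
         else "ICP"
  list(cpg_class = cls, best_oe = w$oe[best], best_gc_at_oe = w$gc[best])
}

#' Classify a set of promoter sequences
#'
#' @param seqs named character vector or `DNAStringSet` of promoter
#'   sequences; names are gene identifiers.
#' @inheritParams classify_promoter
#' @return Data frame with `gene_id`, `best_oe`, `best_gc_at_oe`,
#'   `cpg_class`.
#' @export
classify_promoters <- function(seqs, window = 500L, step = 5L,
                               hcp_oe = 0.75, hcp_gc = 0.55, lcp_oe = 0.48) {
  if (inherits(seqs, "XStringSet")) seqs <- as.character(seqs)
  res <- lapply(seqs, classify_promoter, window = window, step = step,
                hcp_oe = hcp_oe, hcp_gc = hcp_gc, lcp_oe = lcp_oe)
  data.frame(gene_id = names(seqs),
             best_oe = vapply(res, `[[`, 0, "best_oe"),
             best_gc_at_oe = vapply(res, `[[`, 0, "best_gc_at_oe"),
             cpg_class = vapply(res, `[[`, "", "cpg_class"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chi-squared test comparing two CpG-class distributions
#'
#' Pearson chi-squared (no continuity correction) on the 2 x 3 table of
#' class counts of two gene sets, e.g. up-regulated genes against the
#' genomic background.
#'
#' @param classes_a,classes_b character vectors of class labels over
#'   `{HCP, ICP, LCP}`.
#' @return List with the contingency `table`, `statistic`, `df` and `p`.
#' @export
class_distribution_test <- function(classes_a, classes_b) {
  lev <- c("HCP", "ICP", "LCP")
  stopifnot(all(classes_a %in% lev), all(classes_b %in% lev))
  tab <- rbind(a = table(factor(classes_a, levels = lev)),
               b = table(factor(classes_b, levels = lev)))
  use <- colSums(tab) > 0
  obs <- tab[, use, drop = FALSE]
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  if (df < 1 || any(rowSums(obs) == 0)) {
    return(list(table = tab, statistic = 0, df = df, p = 1))
  }
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  stat <- sum((obs - expd)^2 / expd)
  list(table = tab, statistic = stat, df = df,
       p = chisq_pvalue(stat, df))
}
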