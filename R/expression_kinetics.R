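# RPKM-based expression classing, differential calls, kinetic class
# assignment (1hA/3hA/6hA) and the inhibitor-response comparison. The
# differential test is a conditional binomial exact test on pooled counts:
# given the pooled total of a gene, the treated count is binomial with the
# library-size proportion under the null of no change.

#' Differential call per gene from two count vectors
#'
#' Fold changes are computed on library-size-normalized counts (scaled to
#' the mean library) with a pseudocount; the p-value is a two-sided
#' conditional binomial exact test of the treated count against the
#' library-size-proportional expectation given the pooled total.
#'
#' @param counts_ctrl,counts_treat non-negative integer count vectors.
#' @param lib_ctrl,lib_treat library sizes (total mapped tags) of the two
#'   samples.
#' @param fold_min minimum fold change for a call (gate is `>=`).
#' @param p_max p-value threshold (gate is `<`).
#' @param pseudo pseudocount added to both normalized counts.
#' @param gene_id optional identifiers carried into the result.
#' @return Data frame with `gene_id`, `fold` (treated/control), `log2fc`,
#'   `p`, `call` in `{"up", "down", "none"}`.
#' @export
call_differential <- function(counts_ctrl, counts_treat, lib_ctrl, lib_treat,
                              fold_min = 2, p_max = 0.01, pseudo = 0.5,
                              gene_id = NULL) {
  stopifnot(length(counts_ctrl) == length(counts_treat),
            all(counts_ctrl >= 0), all(counts_treat >= 0))
  if (lib_ctrl <= 0 || lib_treat <= 0) stop("library sizes must be positive")
  if (is.null(gene_id)) gene_id <- as.character(seq_along(counts_ctrl))
  mean_lib <- (lib_ctrl + lib_treat) / 2
  nc <- counts_ctrl * mean_lib / lib_ctrl
  nt <- counts_treat * mean_lib / lib_treat
  fold <- (nt + pseudo) / (nc + pseudo)
  pr <- lib_treat / (lib_ctrl + lib_treat)
  pooled <- counts_ctrl + counts_treat
  p <- vapply(seq_along(pooled), function(i) {
    if (pooled[i] == 0) return(1)
    stats::binom.test(counts_treat[i], pooled[i], p = pr)$p.value
  }, 0)
  call <- rep("none", length(fold))
  call[fold >= fold_min & p < p_max] <- "up"
  call[fold <= 1 / fold_min & p < p_max] <- "down"
  data.frame(gene_id = gene_id, fold = fold, log2fc = log2(fold), p = p,
             call = call, stringsAsFactors = FALSE)
}

#' Expression class from control RPKM
#'
#' Default cutoffs: not expressed below log2 RPKM 0 (the detectability
#' boundary), lowly expressed in `[0, 3)`, moderately/highly expressed at
#' `>= 3`; both cutoffs are configurable and inclusive upward.
#'
#' @param rpkm_ctrl non-negative RPKM values.
#' @param low_cut,high_cut log2 RPKM boundaries.
#' @return Character vector over `{"not_expressed", "low",
#'   "moderate_high"}`.
#' @export
expression_class <- function(rpkm_ctrl, low_cut = 0, high_cut = 3) {
  stopifnot(all(rpkm_ctrl >= 0))
  l2 <- log2(rpkm_ctrl)
  ifelse(l2 >= high_cut, "moderate_high",
         ifelse(l2 >= low_cut, "low", "not_expressed"))
}

#' Kinetic class from the three time-point differential calls
#'
#' 1hA: up at 1 h (fold >= 2, p < 0.01). 3hA: fold > 2 at 3 h with
#' p < 0.05 and fold <= 2 at 1 h. 6hA: fold > 2 at 6 h with p < 0.05 and
#' fold <= 2 at both 1 h and 3 h. The two p-value regimes (0.01 at 1 h,
#' 0.05 at the later points) reflect the two analyses they come from and
#' are deliberately not harmonized.
#'
#' @param de_1h,de_3h,de_6h data frames from [call_differential()] for the
#'   three time points, same gene order.
#' @param fold_min fold-change threshold.
#' @param p_1h p gate for the 1 h call.
#' @param p_later p gate for the 3 h / 6 h calls.
#' @return Character vector over `{"1hA", "3hA", "6hA", "none"}`.
#' @export
classify_kinetics <- function(de_1h, de_3h, de_6h, fold_min = 2,
                              p_1h = 0.01, p_later = 0.05) {
  for (d in list(de_1h, de_3h, de_6h)) {
    if (is.null(d) || !all(c("fold", "p") %in% names(d))) {
      stop("all three time points must provide fold and p columns")
    }
  }
  stopifnot(nrow(de_1h) == nrow(de_3h), nrow(de_1h) == nrow(de_6h))
  up1 <- de_1h$fold >= fold_min & de_1h$p < p_1h
  cls <- rep("none", nrow(de_1h))
  cls[up1] <- "1hA"
  is3 <- !up1 & de_1h$fold <= fold_min &
    de_3h$fold > fold_min & de_3h$p < p_later
  cls[is3] <- "3hA"
  is6 <- cls == "none" & de_1h$fold <= fold_min & de_3h$fold <= fold_min &
    de_6h$fold > fold_min & de_6h$p < p_later
  cls[is6] <- "6hA"
  cls
}

#' Reduced induction under kinase inhibition
#'
#' A gene shows reduced induction when its (pseudocounted) fold change with
#' the inhibitor is below the fold change without it.
#'
#' @param de_with,de_without data frames from [call_differential()] for the
#'   matched time point with and without the inhibitor, same gene order.
#' @return Logical vector, `TRUE` where induction is reduced.
#' @export
h89_response <- function(de_with, de_without) {
  stopifnot(nrow(de_with) == nrow(de_without))
  de_with$fold < de_without$fold
}
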