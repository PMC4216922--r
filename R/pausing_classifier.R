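# Promoter-proximal pausing: the pausing index (PI) is the ratio of the
# initiation-competent RNAPII (S5ph) tag density in a TSS window to the
# density over the remaining gene body. PI > 2 together with detectable
# short-capped RNA (scRNA) defines a paused gene; the four-group
# classification of stress-induced genes follows from the PI in both
# conditions, scRNA presence and basal expression.

#' Pausing index per gene
#'
#' `PI = density(TSS window) / density(body)` with the TSS window spanning
#' `(-tss_up, +tss_down)` around the TSS and the body running from
#' `+body_from` to the TES, both strand-oriented; half a tag is added to
#' each region's raw count before forming densities. Genes shorter than
#' `body_from + 300` bp are unclassifiable (`NA`) and reported with a
#' warning.
#'
#' @param track RNAPII S5ph `coverage_track`.
#' @param genes a `gene_models` data frame.
#' @param tss_up,tss_down TSS window extent in bp up-/downstream of the
#'   TSS.
#' @param body_from body start offset downstream of the TSS in bp.
#' @param pseudo tags added to each region count.
#' @return Numeric vector of pausing indices (`NA` for short genes).
#' @export
pausing_index <- function(track, genes, tss_up = 50L, tss_down = 300L,
                          body_from = 300L, pseudo = 0.5) {
  len <- genes$end - genes$start
  short <- len < body_from + 300L
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than ", body_from + 300L,
            " bp are unclassifiable (PI = NA)")
  }
  vapply(seq_len(nrow(genes)), function(i) {
    if (short[i]) return(NA_real_)
    tss_cnt <- sum(oriented_density(track, genes$chrom[i], genes$tss[i],
                                    genes$strand[i], tss_up, tss_down))
    body_len <- len[i] - body_from
    body_cnt <- sum(oriented_density(track, genes$chrom[i], genes$tss[i],
                                     genes$strand[i], -body_from, len[i]))
    tss_dens <- (tss_cnt + pseudo) / (tss_up + tss_down)
    body_dens <- (body_cnt + pseudo) / body_len
    tss_dens / body_dens
  }, 0)
}

#' scRNA presence call
#'
#' @param scrna_count raw scRNA tag count in the TSS window.
#' @param threshold minimum count regarded as presence (inclusive).
#' @return Logical vector.
#' @export
scrna_present <- function(scrna_count, threshold = 5) {
  stopifnot(all(scrna_count >= 0))
  scrna_count >= threshold
}

#' Assemble per-gene pausing records
#'
#' @param gene_id gene identifiers.
#' @param pi_ctrl,pi_aniso pausing indices in the control and stimulated
#'   condition.
#' @param scrna_count scRNA tag counts.
#' @param pi_paused PI threshold above which (with scRNA) a gene is paused.
#' @param scrna_threshold passed to [scrna_present()].
#' @return Data frame with `gene_id`, `pi_ctrl`, `pi_aniso`,
#'   `scrna_present`, `paused_ctrl`.
#' @export
pausing_records <- function(gene_id, pi_ctrl, pi_aniso, scrna_count,
                            pi_paused = 2, scrna_threshold = 5) {
  sc <- scrna_present(scrna_count, scrna_threshold)
  data.frame(gene_id = gene_id, pi_ctrl = pi_ctrl, pi_aniso = pi_aniso,
             scrna_present = sc,
             paused_ctrl = !is.na(pi_ctrl) & pi_ctrl > pi_paused & sc,
             stringsAsFactors = FALSE)
}

#' Four-group classification of stress-induced genes
#'
#' Applies to up-regulated genes: Group I is induced from silence (not
#' expressed basally, not paused, no scRNA); Groups IIA/IIB are paused in
#' the control state and differ in whether the stimulated PI falls below 2
#' (IIA, released) or stays above 2 (IIB); Group III is basally expressed
#' and not paused. A stimulated PI of exactly 2, a missing PI on a paused
#' gene, or any other combination is `"unclassified"`.
#'
#' @param expressed_ctrl logical, basal expression (log2 RPKM >= 0).
#' @param paused_ctrl logical, paused in the control state.
#' @param pi_aniso pausing index in the stimulated condition.
#' @param scrna logical, scRNA presence.
#' @param pi_release PI threshold separating IIA from IIB.
#' @return Character vector over `{"I", "IIA", "IIB", "III",
#'   "unclassified"}`.
#' @export
classify_group <- function(expressed_ctrl, paused_ctrl, pi_aniso, scrna,
                           pi_release = 2) {
  n <- length(expressed_ctrl)
  stopifnot(length(paused_ctrl) == n, length(pi_aniso) == n,
            length(scrna) == n)
  if (any(is.na(expressed_ctrl)) || any(is.na(paused_ctrl))) {
    stop("expression and pausing status must be known for every gene")
  }
  out <- rep("unclassified", n)
  pa <- paused_ctrl
  out[pa & !is.na(pi_aniso) & pi_aniso < pi_release] <- "IIA"
  out[pa & !is.na(pi_aniso) & pi_aniso > pi_release] <- "IIB"
  out[!pa & !expressed_ctrl & !scrna] <- "I"
  out[!pa & expressed_ctrl] <- "III"
  out
}

#' Mark distribution across regulatory groups
#'
#' Builds the 2 x k contingency table of marked status across the groups
#' observed among up-regulated genes and tests association with Fisher's
#' exact test (degenerate tables give p = 1).
#'
#' @param groups group labels from [classify_group()].
#' @param marked logical, marked status of the same genes.
#' @param drop_unclassified exclude `"unclassified"` genes from the table.
#' @return List with the `table` (rows marked/unmarked) and Fisher `p`.
#' @export
group_mark_distribution <- function(groups, marked,
                                    drop_unclassified = TRUE) {
  stopifnot(length(groups) == length(marked))
  if (drop_unclassified) {
    keep <- groups != "unclassified"
    groups <- groups[keep]
    marked <- marked[keep]
  }
  lev <- intersect(c("I", "IIA", "IIB", "III", "unclassified"),
                   unique(groups))
  if (!length(lev)) return(list(table = NULL, p = 1))
  tab <- rbind(marked = table(factor(groups, levels = lev)[marked]),
               unmarked = table(factor(groups, levels = lev)[!marked]))
  list(table = tab, p = fisher_exact_2xk(tab))
}
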