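# Window quantification, RPKM normalization, TSS fold changes and metagene
# profiles. All windows are strand-oriented: "upstream" always means
# upstream relative to the direction of transcription.

# Per-base tag density over genomic [start, end); positions outside the
# chromosome are zero when clip = TRUE, an error otherwise.
track_window_density <- function(track, chrom, start, end, clip = TRUE) {
  if (!chrom %in% names(track$values)) {
    stop("unknown chromosome: ", chrom)
  }
  sz <- track$chrom_sizes[[chrom]]
  if (!clip && (start < 0 || end > sz)) {
    stop(sprintf("window [%s, %s) outside chromosome %s (size %s)",
                 start, end, chrom, sz))
  }
  n <- end - start
  stopifnot(n > 0)
  out <- numeric(n)
  s <- max(start, 0)
  e <- min(end, sz)
  if (s >= e) return(out)
  v <- track$values[[chrom]]
  bin <- track$bin
  idx <- s:(e - 1)
  bins <- idx %/% bin + 1L
  widths <- rep(bin, length(v))
  widths[length(v)] <- sz - (length(v) - 1) * bin
  out[(s - start + 1):(e - start)] <- v[bins] / widths[bins]
  out
}

# Strand-oriented per-base density: element i corresponds to oriented
# offset `offsets[i]` relative to the anchor base, positive offsets lying
# downstream in the direction of transcription.
oriented_density <- function(track, chrom, anchor, strand, up, down,
                             clip = TRUE) {
  if (strand == "-") {
    rev(track_window_density(track, chrom, anchor - down + 1,
                             anchor + up + 1, clip = clip))
  } else {
    track_window_density(track, chrom, anchor - up, anchor + down,
                         clip = clip)
  }
}

#' Raw tag count in a genomic window
#'
#' Sum of per-base tag values over `[start, end)`. With a binned track the
#' count is apportioned by bp overlap, so windows not aligned to bin edges
#' are approximate to within one bin.
#'
#' @param track a `coverage_track`.
#' @param chrom chromosome name.
#' @param start,end window, 0-based half-open.
#' @param clip if `TRUE` (default), the part of the window beyond the
#'   chromosome contributes zero; if `FALSE` such windows are an error.
#' @return Raw tag count (possibly fractional for binned tracks).
#' @export
region_signal <- function(track, chrom, start, end, clip = TRUE) {
  sum(track_window_density(track, chrom, start, end, clip = clip))
}

#' Reads/tags per kilobase per million mapped (RPKM)
#'
#' @param raw_count tag count in the window.
#' @param window_bp window length in bp.
#' @param library_size total mapped tags of the library.
#' @return `raw_count * 1e9 / (window_bp * library_size)`.
#' @export
rpkm <- function(raw_count, window_bp, library_size) {
  stopifnot(all(window_bp > 0))
  if (any(library_size <= 0)) stop("library_size must be positive")
  raw_count * 1e9 / (window_bp * library_size)
}

#' Per-gene log2 fold change of promoter-region signal
#'
#' Signal is quantified as RPKM in a strand-oriented window around the TSS
#' (default -1 kb to +3 kb) in each condition; a pseudocount in RPKM units
#' stabilizes the ratio at low counts.
#'
#' @param track_treat,track_ctrl `coverage_track`s of the two conditions.
#' @param genes a `gene_models` data frame.
#' @param upstream,downstream window extent in bp up-/downstream of the TSS
#'   relative to transcription.
#' @param pseudo_rpkm pseudocount added to both RPKM values.
#' @return Data frame with `gene_id`, `rpkm_treat`, `rpkm_ctrl`, `log2fc`.
#' @export
tss_fold_change <- function(track_treat, track_ctrl, genes,
                            upstream = 1000L, downstream = 3000L,
                            pseudo_rpkm = 0.5) {
  w <- upstream + downstream
  quant <- function(track) {
    cnt <- vapply(seq_len(nrow(genes)), function(i) {
      sum(oriented_density(track, genes$chrom[i], genes$tss[i],
                           genes$strand[i], upstream, downstream))
    }, 0)
    rpkm(cnt, w, track$library_size)
  }
  a <- quant(track_treat)
  b <- quant(track_ctrl)
  data.frame(gene_id = genes$gene_id, rpkm_treat = a, rpkm_ctrl = b,
             log2fc = log2((a + pseudo_rpkm) / (b + pseudo_rpkm)),
             stringsAsFactors = FALSE)
}

profile_bin_means <- function(dens_matrix, bin_bp) {
  nb <- ncol(dens_matrix) / bin_bp
  grp <- rep(seq_len(nb), each = bin_bp)
  t(apply(dens_matrix, 1, function(r) tapply(r, grp, mean)))
}

#' Metagene profile anchored at the TSS or TES
#'
#' Per-gene, per-base tag density (normalized to tags per bp per million
#' mapped) is extracted in a strand-oriented window around the anchor,
#' averaged within fixed-width bins and then across the genes of each
#' stratum. Minus-strand genes are reversed so that downstream of the
#' anchor is always to the right.
#'
#' @param track a `coverage_track`.
#' @param genes a `gene_models` data frame.
#' @param anchor `"tss"` or `"tes"`.
#' @param flank_bp half-width of the window; must be a multiple of
#'   `bin_bp`.
#' @param bin_bp profile bin width in bp.
#' @param strata optional vector of stratum labels, one per gene (e.g.
#'   expression classes); `NULL` profiles all genes together. Empty strata
#'   are dropped with a warning.
#' @return Data frame with `stratum`, `offset` (oriented bp offset of the
#'   bin start relative to the anchor), `mean_density`, `n_genes`.
#' @export
anchored_profile <- function(track, genes, anchor = c("tss", "tes"),
                             flank_bp = 2000L, bin_bp = 25L, strata = NULL) {
  anchor <- match.arg(anchor)
  if (flank_bp %% bin_bp != 0) stop("flank_bp must be a multiple of bin_bp")
  if (is.null(strata)) strata <- rep("all", nrow(genes))
  stopifnot(length(strata) == nrow(genes))
  anchors <- if (anchor == "tss") genes$tss else genes$tes
  dens <- t(vapply(seq_len(nrow(genes)), function(i) {
    oriented_density(track, genes$chrom[i], anchors[i], genes$strand[i],
                     flank_bp, flank_bp)
  }, numeric(2 * flank_bp)))
  dens <- dens * 1e6 / track$library_size
  binned <- profile_bin_means(dens, bin_bp)
  offsets <- seq(-flank_bp, flank_bp - bin_bp, by = bin_bp)
  out <- lapply(unique(strata), function(s) {
    i <- which(strata == s)
    if (!length(i)) return(NULL)
    data.frame(stratum = s, offset = offsets,
               mean_density = colMeans(binned[i, , drop = FALSE]),
               n_genes = length(i), stringsAsFactors = FALSE)
  })
  empty <- setdiff(unique(strata), unlist(lapply(out, function(d) d$stratum[1])))
  if (length(empty)) warning("dropping empty strata: ",
                             paste(empty, collapse = ", "))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Scaled-body metagene profile
#'
#' Each gene body is rescaled to `n_bins` equal fractional bins (mean
#' per-base density per bin) with fixed-resolution flanks upstream of the
#' TSS and downstream of the TES; genes shorter than `n_bins` bp are
#' excluded with a warning.
#'
#' @inheritParams anchored_profile
#' @param n_bins number of fractional bins the body is rescaled to.
#' @param flank_bin_bp bin width of the fixed-resolution flanks.
#' @return Data frame with `segment` (`"upstream"`, `"body"`,
#'   `"downstream"`), `bin` (1-based index within segment), `mean_density`,
#'   `n_genes`.
#' @export
scaled_body_profile <- function(track, genes, n_bins = 100L,
                                flank_bp = 2000L, flank_bin_bp = 25L) {
  if (flank_bp %% flank_bin_bp != 0) {
    stop("flank_bp must be a multiple of flank_bin_bp")
  }
  len <- genes$end - genes$start
  keep <- len >= n_bins
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) shorter than ", n_bins, " bp excluded")
    genes <- genes[keep, , drop = FALSE]
    len <- len[keep]
  }
  if (!nrow(genes)) stop("no genes long enough to profile")
  nfb <- flank_bp / flank_bin_bp
  rows <- vapply(seq_len(nrow(genes)), function(i) {
    L <- len[i]
    body <- oriented_density(track, genes$chrom[i], genes$tss[i],
                             genes$strand[i], 0, L)
    up <- oriented_density(track, genes$chrom[i], genes$tss[i],
                           genes$strand[i], flank_bp, 0)
    dn <- oriented_density(track, genes$chrom[i], genes$tes[i],
                           genes$strand[i], -1, flank_bp + 1)
    edges <- floor((0:n_bins) * L / n_bins)
    body_bins <- vapply(seq_len(n_bins), function(j) {
      mean(body[(edges[j] + 1):edges[j + 1]])
    }, 0)
    upg <- rep(seq_len(nfb), each = flank_bin_bp)
    c(tapply(up, upg, mean), body_bins, tapply(dn, upg, mean))
  }, numeric(2 * nfb + n_bins))
  rows <- t(rows) * 1e6 / track$library_size
  data.frame(segment = rep(c("upstream", "body", "downstream"),
                           c(nfb, n_bins, nfb)),
             bin = c(seq_len(nfb), seq_len(n_bins), seq_len(nfb)),
             mean_density = colMeans(rows),
             n_genes = nrow(genes), stringsAsFactors = FALSE)
}

#' Spearman rank correlation
#'
#' Midrank tie handling; constant input is an error (the correlation is
#' undefined).
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return Spearman's rho in `[-1, 1]`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "spearman")
}
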