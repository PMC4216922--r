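# Gene-level calling of the stress-induced mark. A windowed Poisson
# enrichment test against a background track stands in for peak calling:
# the decision rule (fold enrichment >= 5 at FDR <= 0.05) operates on
# promoter-window tag counts scaled by library size.

#' Call marked genes from ChIP and background coverage
#'
#' For each gene the ChIP tag count in a strand-oriented promoter window is
#' compared with the library-size-scaled background count: the expected
#' count is `background * lib_chip / lib_background + 1` (one pseudo-tag
#' guards empty windows), the p-value is the Poisson upper tail
#' `P(X >= chip)` at that expectation, and q-values control the FDR across
#' all genes. A gene is marked when it passes both the fold and FDR gates.
#'
#' @param chip,background `coverage_track`s; the background is a matched
#'   input, or the untreated ChIP when no input is available.
#' @param genes a `gene_models` data frame.
#' @param upstream,downstream promoter window extent around the TSS
#'   (default TSS +/- 500 bp).
#' @param fold_min minimum fold enrichment.
#' @param fdr_max maximum q-value.
#' @param method multiple-testing procedure, `"BH"` (default) or
#'   `"hochberg"`.
#' @return Data frame with `gene_id`, `chip_count`, `background_count`,
#'   `fold_enrichment`, `p`, `q`, `marked`.
#' @export
call_marked_genes <- function(chip, background, genes,
                              upstream = 500L, downstream = 500L,
                              fold_min = 5, fdr_max = 0.05,
                              method = c("BH", "hochberg")) {
  method <- match.arg(method)
  if (background$library_size <= 0) stop("background library_size must be > 0")
  count_in_window <- function(track) {
    vapply(seq_len(nrow(genes)), function(i) {
      sum(oriented_density(track, genes$chrom[i], genes$tss[i],
                           genes$strand[i], upstream, downstream))
    }, 0)
  }
  chip_count <- count_in_window(chip)
  bg_count <- count_in_window(background)
  expected <- bg_count * chip$library_size / background$library_size + 1
  fold <- chip_count / expected
  p <- stats::ppois(chip_count - 1, lambda = expected, lower.tail = FALSE)
  q <- adjust_pvalues(p, method = method)
  data.frame(gene_id = genes$gene_id, chip_count = chip_count,
             background_count = bg_count, fold_enrichment = fold,
             p = p, q = q, marked = q <= fdr_max & fold >= fold_min,
             stringsAsFactors = FALSE)
}

FEATURE_LEVELS <- c("promoter", "utr5", "cds", "intron", "utr3", "intergenic")

ranges_by_chrom <- function(df) {
  lapply(split(df, df$chrom), function(d) {
    IRanges::IRanges(start = d$start + 1, end = d$end)
  })
}

# Per-gene structural intervals (0-based half-open data frames).
gene_feature_intervals <- function(genes, promoter_bp = 1000L) {
  n <- nrow(genes)
  prom <- utr5 <- utr3 <- cds <- intron <- vector("list", n)
  has_struct <- !is.null(genes$exons) && !is.null(genes$thick_start)
  for (i in seq_len(n)) {
    st <- genes$strand[i]
    gs <- genes$start[i]; ge <- genes$end[i]
    prom[[i]] <- if (st == "+") c(max(0, gs - promoter_bp), gs)
                 else c(ge, ge + promoter_bp)
    if (has_struct && !is.na(genes$thick_start[i])) {
      ex <- genes$exons[[i]]
      ts <- genes$thick_start[i]; te <- genes$thick_end[i]
      clip <- function(a, b) {
        seg <- cbind(pmax(ex[, 1], a), pmin(ex[, 2], b))
        seg[seg[, 1] < seg[, 2], , drop = FALSE]
      }
      left <- clip(gs, ts)   # exonic bp left of the CDS
      right <- clip(te, ge)  # exonic bp right of the CDS
      cds[[i]] <- clip(ts, te)
      if (st == "+") { utr5[[i]] <- left; utr3[[i]] <- right }
      else { utr5[[i]] <- right; utr3[[i]] <- left }
      # introns: gene bp not covered by exons
      gaps <- cbind(c(gs, ex[, 2]), c(ex[, 1], ge))
      intron[[i]] <- gaps[gaps[, 1] < gaps[, 2], , drop = FALSE]
    } else {
      cds[[i]] <- cbind(gs, ge)
    }
  }
  to_df <- function(lst) {
    m <- do.call(rbind, lapply(seq_len(n), function(i) {
      x <- lst[[i]]
      if (is.null(x) || !length(x)) return(NULL)
      x <- matrix(x, ncol = 2)
      cbind(i, x)
    }))
    if (is.null(m)) {
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric()))
    }
    data.frame(chrom = genes$chrom[m[, 1]], start = m[, 2], end = m[, 3],
               stringsAsFactors = FALSE)
  }
  list(promoter = to_df(prom), utr5 = to_df(utr5), cds = to_df(cds),
       intron = to_df(intron), utr3 = to_df(utr3))
}

#' Precompute a precedence-resolved genomic feature map
#'
#' The promoter is the 1 kb upstream of the TSS; the gene body contributes
#' 5'UTR, CDS, intron and 3'UTR (gene models without exon/CDS structure
#' count their whole body as CDS); everything else is intergenic. Features
#' are resolved with precedence promoter > 5'UTR > CDS > intron > 3'UTR >
#' intergenic so that the per-bp fractions partition the genome exactly.
#'
#' @param genes a `gene_models` data frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param promoter_bp promoter width upstream of the TSS.
#' @return An object of class `feature_map` holding per-feature interval
#'   sets and genome background fractions (summing to 1).
#' @export
build_feature_map <- function(genes, chrom_sizes, promoter_bp = 1000L) {
  feats <- gene_feature_intervals(genes, promoter_bp = promoter_bp)
  chroms <- names(chrom_sizes)
  resolved <- list()
  occupied <- lapply(chroms, function(ch) IRanges::IRanges())
  names(occupied) <- chroms
  for (f in names(feats)) {
    by_chr <- ranges_by_chrom(feats[[f]])
    res <- list()
    for (ch in chroms) {
      ir <- if (ch %in% names(by_chr)) IRanges::reduce(by_chr[[ch]])
            else IRanges::IRanges()
      # clip to chromosome, then remove bp claimed by higher precedence
      ir <- IRanges::restrict(ir, start = 1L, end = as.integer(chrom_sizes[[ch]]))
      ir <- IRanges::setdiff(ir, occupied[[ch]])
      occupied[[ch]] <- IRanges::reduce(c(occupied[[ch]], ir))
      res[[ch]] <- ir
    }
    resolved[[f]] <- res
  }
  genome_bp <- sum(chrom_sizes)
  feature_bp <- vapply(resolved, function(res) {
    sum(vapply(res, function(ir) sum(IRanges::width(ir)), 0))
  }, 0)
  fractions <- c(feature_bp, intergenic = genome_bp - sum(feature_bp)) /
    genome_bp
  structure(list(resolved = resolved, fractions = fractions,
                 chrom_sizes = chrom_sizes),
            class = "feature_map")
}

#' Assign regions to gene features by midpoint
#'
#' Each region receives the single feature label of its midpoint under the
#' precedence promoter > 5'UTR > CDS > intron > 3'UTR > intergenic.
#'
#' @param regions interval data frame (`chrom`, `start`, `end`).
#' @param fmap a `feature_map` from [build_feature_map()].
#' @return Character vector of feature labels.
#' @export
assign_region_feature <- function(regions, fmap) {
  mid <- floor((regions$start + regions$end) / 2)
  out <- rep("intergenic", nrow(regions))
  for (f in names(fmap$resolved)) {
    unassigned <- out == "intergenic"
    for (ch in unique(regions$chrom[unassigned])) {
      i <- which(unassigned & regions$chrom == ch)
      if (!ch %in% names(fmap$resolved[[f]])) next
      q <- IRanges::IRanges(start = mid[i] + 1, width = 1)
      hit <- IRanges::overlapsAny(q, fmap$resolved[[f]][[ch]])
      out[i[hit]] <- f
    }
  }
  out
}

#' Feature enrichment of a region set over the genome background
#'
#' Counts region midpoints per feature and tests each against the genomic
#' background fraction of that feature with a one-sided binomial test.
#'
#' @inheritParams assign_region_feature
#' @return Data frame with one row per feature: `feature`,
#'   `n_regions_in_feature`, `n_regions_total`, `background_fraction`,
#'   `fold`, `p`. Zero regions give an empty result.
#' @export
feature_enrichment <- function(regions, fmap) {
  n <- nrow(regions)
  if (n == 0) {
    return(data.frame(feature = character(), n_regions_in_feature = integer(),
                      n_regions_total = integer(),
                      background_fraction = numeric(), fold = numeric(),
                      p = numeric()))
  }
  labels <- assign_region_feature(regions, fmap)
  counts <- table(factor(labels, levels = FEATURE_LEVELS))
  frac <- fmap$fractions[FEATURE_LEVELS]
  k <- as.integer(counts)
  p <- vapply(seq_along(k), function(i) {
    if (frac[i] <= 0) return(if (k[i] > 0) 0 else 1)
    if (frac[i] >= 1) return(1)
    binomial_onesided(k[i], n, frac[i])
  }, 0)
  data.frame(feature = FEATURE_LEVELS, n_regions_in_feature = k,
             n_regions_total = n, background_fraction = as.numeric(frac),
             fold = (k / n) / as.numeric(frac), p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of regions overlapping CpG islands
#'
#' @param regions interval data frame (`chrom`, `start`, `end`).
#' @param islands CpG-island interval data frame in the same form.
#' @return Fraction of `regions` sharing at least one bp with an island.
#' @export
cpg_island_overlap <- function(regions, islands) {
  if (nrow(regions) == 0) return(0)
  isl <- ranges_by_chrom(islands)
  hits <- logical(nrow(regions))
  for (ch in unique(regions$chrom)) {
    i <- which(regions$chrom == ch)
    if (!ch %in% names(isl)) next
    q <- IRanges::IRanges(start = regions$start[i] + 1, end = regions$end[i])
    hits[i] <- IRanges::overlapsAny(q, isl[[ch]])
  }
  mean(hits)
}
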