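# Seeded synthetic-data generator. One synthetic chromosome carries
# non-overlapping genes with exon/CDS structure; ground-truth labels
# (marked, paused, released, kinetic class, expression, CpG class) are
# drawn by exact quota sampling and every downstream observable -- ChIP
# coverage, expression counts, short-capped RNA, promoter sequence -- is
# generated from those labels with Poisson sequencing noise, so the full
# pipeline can be scored against known truth.

SIM_TRACKS <- c("H3S28ph", "H3K9ac", "H3K4me3", "RNAPIIS5ph", "RNAPIIS2ph",
                "input")
SIM_CONDITIONS <- c("ctrl", "aniso")

#' Simulation configuration
#'
#' Defaults describe the reference simulation used by the validation suite:
#' 2,000 genes on one synthetic chromosome, sequencing depth of 100 tags
#' per expressed-gene kb, ten-fold promoter mark deposition in the
#' stimulated condition only, eight-fold TSS concentration of initiating
#' RNAPII at paused genes, and three disjoint kinetic induction classes.
#'
#' @param n_genes number of genes.
#' @param genome_size chromosome length in bp.
#' @param bin coverage bin width in bp.
#' @param fraction_expressed fraction of genes expressed basally
#'   (log2 RPKM >= 0).
#' @param fraction_marked fraction of genes receiving the stress mark.
#' @param fraction_paused fraction of genes with promoter-proximal paused
#'   RNAPII (a subset of the expressed genes).
#' @param fractions_induced named fractions for the `1hA`, `3hA`, `6hA`
#'   kinetic classes (disjoint).
#' @param fraction_released fraction of paused genes released into
#'   elongation upon stimulation.
#' @param induced_fold_change expression fold change reached by induced
#'   genes at and after their class time point (>= 2).
#' @param mark_enrichment promoter mark density over background at marked
#'   genes (stimulated condition).
#' @param pausing_enrichment TSS over gene-body RNAPII density at paused
#'   genes.
#' @param depth mean tags per expressed-gene kb; scales every track and
#'   count table.
#' @param cpg_class_mix named proportions of `HCP`, `ICP`, `LCP` promoter
#'   classes (sum to 1).
#' @param acetylation_coupling additive log2 promoter acetylation gain at
#'   marked induced genes in the stimulated condition.
#' @param h89_suppression residual fraction of the induction retained under
#'   kinase inhibition at marked genes (0 = full block, 1 = no effect).
#' @param scrna_scale scRNA mean per expected TSS-window RNAPII S5ph tag at
#'   paused genes.
#' @param overdispersion gamma overdispersion of all Poisson rates
#'   (0 = pure Poisson).
#' @param seed integer seed; every generator derives its stream from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, genome_size = 3.2e7, bin = 25L,
                       fraction_expressed = 0.5, fraction_marked = 0.12,
                       fraction_paused = 0.3,
                       fractions_induced = c("1hA" = 0.05, "3hA" = 0.05,
                                             "6hA" = 0.04),
                       fraction_released = 0.5, induced_fold_change = 4,
                       mark_enrichment = 10, pausing_enrichment = 8,
                       depth = 100, cpg_class_mix = c(HCP = 0.5, ICP = 0.3,
                                                      LCP = 0.2),
                       acetylation_coupling = 1, h89_suppression = 0.25,
                       scrna_scale = 0.4, overdispersion = 0, seed = 1L) {
  fr <- c(fraction_expressed, fraction_marked, fraction_paused,
          fractions_induced, fraction_released)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (sum(fractions_induced) > 1) stop("induced fractions exceed 1")
  if (fraction_paused > fraction_expressed) {
    stop("paused genes are a subset of expressed genes: fraction_paused ",
         "must not exceed fraction_expressed")
  }
  stopifnot(length(fractions_induced) == 3,
            all(c("1hA", "3hA", "6hA") %in% names(fractions_induced)))
  if (abs(sum(cpg_class_mix) - 1) > 1e-8) stop("cpg_class_mix must sum to 1")
  stopifnot(all(c("HCP", "ICP", "LCP") %in% names(cpg_class_mix)))
  if (depth < 0) stop("depth must be non-negative")
  if (induced_fold_change < 2) stop("induced_fold_change must be >= 2")
  structure(list(n_genes = as.integer(n_genes), genome_size = genome_size,
                 bin = as.integer(bin),
                 fraction_expressed = fraction_expressed,
                 fraction_marked = fraction_marked,
                 fraction_paused = fraction_paused,
                 fractions_induced = fractions_induced,
                 fraction_released = fraction_released,
                 induced_fold_change = induced_fold_change,
                 mark_enrichment = mark_enrichment,
                 pausing_enrichment = pausing_enrichment, depth = depth,
                 cpg_class_mix = cpg_class_mix,
                 acetylation_coupling = acetylation_coupling,
                 h89_suppression = h89_suppression,
                 scrna_scale = scrna_scale,
                 overdispersion = overdispersion, seed = as.integer(seed)),
            class = "sim_config")
}

# Oriented genomic window (0-based half-open): up/down are bp up- and
# downstream of the anchor base relative to transcription.
oriented_window <- function(anchor, strand, up, down) {
  if (strand == "-") c(anchor - down + 1, anchor + up + 1)
  else c(anchor - up, anchor + down)
}

# Exact quota: round(frac * n) items sampled uniformly from idx.
quota_sample <- function(idx, frac) {
  k <- round(frac * length(idx))
  if (k == 0) return(integer(0))
  sample(idx, k)
}

# Quota split into labelled classes by largest remainder.
quota_classes <- function(n, mix) {
  k <- floor(mix * n)
  rem <- mix * n - k
  short <- n - sum(k)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    k[add] <- k[add] + 1
  }
  sample(rep(names(mix), k))
}

# Genomic coordinate reached after skipping k exonic bases from the left
# (or right) edge of an exon matrix.
exonic_offset <- function(ex, k, from_left = TRUE) {
  if (!from_left) {
    ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  }
  for (i in seq_len(nrow(ex))) {
    w <- ex[i, 2] - ex[i, 1]
    if (k < w) {
      return(if (from_left) ex[i, 1] + k else ex[i, 2] - k)
    }
    k <- k - w
  }
  if (from_left) ex[nrow(ex), 2] else ex[1, 1]
}

#' Simulate the gene annotation and ground-truth labels
#'
#' Places `n_genes` non-overlapping genes of 1-20 kb with >= 2 kb spacing
#' on one synthetic chromosome, draws every ground-truth label by exact
#' quota sampling, and emits CpG islands over the promoters of HCP genes.
#' Fully deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return List with `genes` (a `gene_models` data frame with exon/CDS
#'   structure), `truth` (per-gene label data frame including `true_group`
#'   and the latent expression levels), `islands` (CpG-island intervals)
#'   and `chrom_sizes`.
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  len <- round(stats::runif(n, 1000, 20000))
  gap <- round(stats::runif(n, 2000, 4000))
  start <- cumsum(gap) + cumsum(c(0, len[-n]))
  end <- start + len
  if (end[n] + 1000 > config$genome_size) {
    stop(sprintf("cannot place %d genes of 1-20 kb in a %.0f bp genome",
                 n, config$genome_size))
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  exons <- vector("list", n)
  thick_s <- thick_e <- numeric(n)
  for (i in seq_len(n)) {
    n_ex <- sample(2:max(2, min(8, floor(len[i] / 400))), 1)
    nseg <- 2 * n_ex - 1
    w <- stats::runif(nseg, 0.5, 1.5)
    seg <- floor(len[i] * w / sum(w))
    seg[nseg] <- len[i] - sum(seg[-nseg])
    bounds <- start[i] + cumsum(c(0, seg))
    ex <- cbind(bounds[seq(1, nseg, by = 2)], bounds[seq(2, nseg + 1, by = 2)])
    exonic <- sum(ex[, 2] - ex[, 1])
    u5 <- round(stats::runif(1, 50, 150))
    u3 <- round(stats::runif(1, 100, 300))
    if (u5 + u3 > exonic - 100) {
      scale <- (exonic - 100) / (u5 + u3)
      u5 <- floor(u5 * scale)
      u3 <- floor(u3 * scale)
    }
    left <- if (strand[i] == "+") u5 else u3
    right <- if (strand[i] == "+") u3 else u5
    exons[[i]] <- ex
    thick_s[i] <- exonic_offset(ex, left, from_left = TRUE)
    thick_e[i] <- exonic_offset(ex, right, from_left = FALSE)
  }
  gene_id <- sprintf("g%04d", seq_len(n))
  genes <- gene_models(gene_id, "chrS", start, end, strand, exons = exons,
                       thick_start = thick_s, thick_end = thick_e)

  expressed <- logical(n)
  expressed[quota_sample(seq_len(n), config$fraction_expressed)] <- TRUE
  paused <- logical(n)
  paused_quota <- round(config$fraction_paused * n)
  if (paused_quota > sum(expressed)) stop("not enough expressed genes to pause")
  paused[sample(which(expressed), paused_quota)] <- TRUE
  marked <- logical(n)
  marked[quota_sample(seq_len(n), config$fraction_marked)] <- TRUE
  pool <- sample(seq_len(n))
  kin <- rep("none", n)
  taken <- 0
  for (cl in c("1hA", "3hA", "6hA")) {
    k <- round(config$fractions_induced[[cl]] * n)
    if (k > 0) kin[pool[taken + seq_len(k)]] <- cl
    taken <- taken + k
  }
  released <- logical(n)
  released[paused] <- stats::runif(sum(paused)) < config$fraction_released
  cpg_class <- quota_classes(n, config$cpg_class_mix)
  base_rpkm <- ifelse(expressed, 2^stats::runif(n, 0.8, 8),
                      2^stats::runif(n, -5, -2))
  induced_target <- ifelse(!expressed & kin != "none",
                           2^stats::runif(n, 1, 4), NA)
  up1 <- kin == "1hA"
  true_group <- rep("none", n)
  true_group[up1 & paused & released] <- "IIA"
  true_group[up1 & paused & !released] <- "IIB"
  true_group[up1 & !paused & !expressed] <- "I"
  true_group[up1 & !paused & expressed] <- "III"
  truth <- data.frame(gene_id = gene_id, marked = marked,
                      expressed_ctrl = expressed, paused = paused,
                      released_on_stimulus = released, kinetic_class = kin,
                      cpg_class = cpg_class, true_group = true_group,
                      base_rpkm = base_rpkm, induced_target = induced_target,
                      stringsAsFactors = FALSE)
  prom <- t(vapply(seq_len(n), function(i) {
    oriented_window(genes$tss[i], strand[i], 700, 300)
  }, numeric(2)))
  hcp <- cpg_class == "HCP"
  islands <- data.frame(chrom = "chrS",
                        start = pmax(0, prom[hcp, 1]),
                        end = pmin(config$genome_size, prom[hcp, 2]),
                        stringsAsFactors = FALSE)
  list(genes = genes, truth = truth, islands = islands,
       chrom_sizes = c(chrS = config$genome_size))
}

# Latent expected RPKM for every gene at a given time point and arm,
# deterministic given the truth table.
expected_rpkm <- function(truth, config, time, arm = c("ctrl", "h89")) {
  arm <- match.arg(arm)
  time_of <- c("1hA" = 1, "3hA" = 3, "6hA" = 6)
  on <- truth$kinetic_class != "none" &
    time >= time_of[truth$kinetic_class]
  on[is.na(on)] <- FALSE
  r <- truth$base_rpkm
  r[on] <- ifelse(truth$expressed_ctrl[on],
                  truth$base_rpkm[on] * config$induced_fold_change,
                  truth$induced_target[on])
  if (arm == "h89") {
    blocked <- on & truth$marked
    r[blocked] <- truth$base_rpkm[blocked] +
      (r[blocked] - truth$base_rpkm[blocked]) * config$h89_suppression
  }
  r
}

sim_rpois <- function(n, lambda, overdispersion) {
  if (overdispersion > 0) {
    shape <- 1 / overdispersion
    lambda <- lambda * stats::rgamma(n, shape = shape, rate = shape)
  }
  stats::rpois(n, lambda)
}

#' Simulate ChIP-seq coverage for one track and condition
#'
#' Coverage is Poisson tag noise around a deterministic expected density:
#' a uniform background of `depth / 1000` tags per bp, the promoter mark at
#' `mark_enrichment` times background over TSS +/- 500 bp of marked genes
#' (stimulated condition only), acetylation/methylation promoter signal at
#' expressed genes with the configured acetylation gain at marked induced
#' genes, and RNAPII body density proportional to expression with
#' `pausing_enrichment`-fold TSS concentration at paused genes (which
#' relaxes upon stimulation at released genes).
#'
#' @param annotation result of [simulate_annotation()].
#' @param config the same [sim_config()].
#' @param track one of `"H3S28ph"`, `"H3K9ac"`, `"H3K4me3"`,
#'   `"RNAPIIS5ph"`, `"RNAPIIS2ph"`, `"input"`.
#' @param condition `"ctrl"` or `"aniso"`.
#' @return A `coverage_track` binned at `config$bin`.
#' @export
simulate_coverage <- function(annotation, config, track, condition = "ctrl") {
  if (!track %in% SIM_TRACKS) stop("unknown track label: ", track)
  if (!condition %in% SIM_CONDITIONS) stop("unknown condition: ", condition)
  set.seed(config$seed + 1000L * match(track, SIM_TRACKS) +
             match(condition, SIM_CONDITIONS))
  genes <- annotation$genes
  truth <- annotation$truth
  bin <- config$bin
  size <- config$genome_size
  n_bins <- ceiling(size / bin)
  r0 <- config$depth / 1000
  add <- function(rate, i, up, down, dens, anchor = genes$tss[i]) {
    w <- oriented_window(anchor, genes$strand[i], up, down)
    add_window_counts(rate, max(0, w[1]), min(size, w[2]), dens, bin)
  }
  stim <- condition == "aniso"
  rpkm_now <- expected_rpkm(truth, config, time = if (stim) 1 else 0)
  induced_now <- rpkm_now > truth$base_rpkm

  rate <- rep(r0 * bin, n_bins)
  if (track == "input") {
    # flat background only
  } else if (track == "H3S28ph") {
    if (stim) {
      for (i in which(truth$marked)) {
        rate <- add(rate, i, 500, 500, (config$mark_enrichment - 1) * r0)
      }
    }
  } else if (track %in% c("H3K9ac", "H3K4me3")) {
    rate <- rep(0.2 * r0 * bin, n_bins)
    gain <- 2^config$acetylation_coupling
    for (i in which(truth$expressed_ctrl | induced_now)) {
      dens <- 4 * r0
      if (track == "H3K9ac" && stim && truth$marked[i] && induced_now[i]) {
        dens <- dens * gain
      }
      rate <- add(rate, i, 500, 500, dens)
    }
  } else { # RNAPII S5ph / S2ph
    rate <- rep(0.02 * r0 * bin, n_bins)
    w_expr <- rpkm_now / 8
    for (i in which(rpkm_now >= 1)) {
      b <- w_expr[i] * r0
      L <- genes$end[i] - genes$start[i]
      if (track == "RNAPIIS5ph") {
        rate <- add(rate, i, 0, L, b)
        paused_now <- truth$paused[i] &&
          (!stim || !truth$released_on_stimulus[i])
        if (paused_now) {
          rate <- add(rate, i, 50, 300, (config$pausing_enrichment - 1) * b)
        }
      } else {
        rate <- add(rate, i, -300, L, b)
      }
    }
  }
  values <- list(chrS = sim_rpois(n_bins, rate, config$overdispersion))
  coverage_track(values, annotation$chrom_sizes, bin = bin,
                 label = track, condition = condition)
}

#' Simulate expression count tables
#'
#' One sample per time point (0, 1, 3, 6 h) and arm (without / with the
#' kinase inhibitor). Counts are Poisson around the latent per-gene RPKM
#' trajectory: induced genes reach the configured fold change at and after
#' their class time point (silent genes are induced to an expressed target
#' level), the inhibitor arm retains only `h89_suppression` of the
#' induction at marked genes, and library sizes are constant across
#' samples.
#'
#' @inheritParams simulate_coverage
#' @return List with `counts` (genes x samples matrix), `rpkm` (realized
#'   RPKM from the counts), `lib_sizes`, and `samples` (time / arm per
#'   column).
#' @export
simulate_expression_tables <- function(annotation, config) {
  set.seed(config$seed + 101L)
  truth <- annotation$truth
  genes <- annotation$genes
  len_kb <- (genes$end - genes$start) / 1000
  C <- config$depth / 10
  times <- c(0, 1, 3, 6)
  arms <- c("ctrl", "h89")
  samples <- expand.grid(time = times, arm = arms,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lib <- round(C * 1e6)
  counts <- sapply(seq_len(nrow(samples)), function(j) {
    lambda <- expected_rpkm(truth, config, samples$time[j], samples$arm[j]) *
      len_kb * C
    sim_rpois(length(lambda), lambda, config$overdispersion)
  })
  colnames(counts) <- paste0("t", samples$time, "_", samples$arm)
  rownames(counts) <- truth$gene_id
  lib_sizes <- stats::setNames(rep(lib, ncol(counts)), colnames(counts))
  rpkm_mat <- if (lib > 0) {
    sweep(counts * 1e9, 1, len_kb * 1000, "/") / lib
  } else {
    counts * NA_real_
  }
  list(counts = counts, rpkm = rpkm_mat, lib_sizes = lib_sizes,
       samples = samples)
}

#' Simulate short-capped RNA counts
#'
#' Paused genes receive counts whose mean is proportional to the expected
#' TSS-window RNAPII S5ph tag count; all other genes receive a low
#' background well below the presence threshold.
#'
#' @inheritParams simulate_coverage
#' @return Data frame with `gene_id`, `scrna_count`.
#' @export
simulate_scrna <- function(annotation, config) {
  set.seed(config$seed + 55L)
  truth <- annotation$truth
  r0 <- config$depth / 1000
  tss_tags <- config$pausing_enrichment * (truth$base_rpkm / 8) * r0 * 350
  lambda <- ifelse(truth$paused, config$scrna_scale * tss_tags,
                   0.005 * config$depth)
  data.frame(gene_id = truth$gene_id,
             scrna_count = sim_rpois(nrow(truth), lambda,
                                     config$overdispersion),
             stringsAsFactors = FALSE)
}

CPG_CLASS_PARAMS <- list(
  HCP = list(gc = 0.65, keep = 1.00),
  ICP = list(gc = 0.48, keep = 0.60),
  LCP = list(gc = 0.40, keep = 0.12)
)

#' Simulate promoter sequences
#'
#' One 1 kb sequence per gene (-700..+300 of the TSS) generated so that
#' its realized CpG observed/expected ratio and GC content fall in the
#' generating class's target range: bases are drawn i.i.d. at the class GC
#' content (which yields o/e near 1) and CpG dinucleotides are then thinned
#' to the class target by replacing the G of a discarded CpG with A or T.
#'
#' @inheritParams simulate_coverage
#' @return A named `DNAStringSet` (names are gene identifiers).
#' @export
simulate_promoter_sequences <- function(annotation, config) {
  set.seed(config$seed + 77L)
  truth <- annotation$truth
  seqs <- vapply(seq_len(nrow(truth)), function(i) {
    par <- CPG_CLASS_PARAMS[[truth$cpg_class[i]]]
    p <- c(A = (1 - par$gc) / 2, C = par$gc / 2, G = par$gc / 2,
           T = (1 - par$gc) / 2)
    s <- sample(names(p), 1000, replace = TRUE, prob = p)
    if (par$keep < 1) {
      cg <- which(s[-1000] == "C" & s[-1] == "G")
      drop <- cg[stats::runif(length(cg)) >= par$keep]
      if (length(drop)) {
        s[drop + 1] <- sample(c("A", "T"), length(drop), replace = TRUE)
      }
    }
    paste(s, collapse = "")
  }, "")
  Biostrings::DNAStringSet(stats::setNames(seqs, truth$gene_id))
}

#' Simulate a complete dataset
#'
#' Runs every generator off one configuration and optionally writes the
#' standard file bundle (genes.bed, truth.tsv, chrom.sizes, bedGraph
#' tracks, expression and scRNA tables, promoters.fa, cpg_islands.bed).
#'
#' @param config a [sim_config()].
#' @param tracks character vector of `"track_condition"` combinations to
#'   simulate (default: the tracks the full pipeline consumes).
#' @param outdir optional output directory.
#' @return List with `config`, `genes`, `truth`, `islands`, `chrom_sizes`,
#'   `tracks` (named list of `coverage_track`s), `expr`, `scrna`,
#'   `promoters`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             tracks = c("H3S28ph_ctrl", "H3S28ph_aniso",
                                        "input_ctrl", "RNAPIIS5ph_ctrl",
                                        "RNAPIIS5ph_aniso", "H3K9ac_ctrl",
                                        "H3K9ac_aniso"),
                             outdir = NULL) {
  ann <- simulate_annotation(config)
  cov <- lapply(tracks, function(tc) {
    parts <- strsplit(tc, "_", fixed = TRUE)[[1]]
    simulate_coverage(ann, config, parts[1], parts[2])
  })
  names(cov) <- tracks
  expr <- simulate_expression_tables(ann, config)
  scrna <- simulate_scrna(ann, config)
  promoters <- simulate_promoter_sequences(ann, config)
  out <- list(config = config, genes = ann$genes, truth = ann$truth,
              islands = ann$islands, chrom_sizes = ann$chrom_sizes,
              tracks = cov, expr = expr, scrna = scrna,
              promoters = promoters)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_gene_models(ann$genes, file.path(outdir, "genes.bed"))
    write_record_table(ann$truth, file.path(outdir, "truth.tsv"))
    writeLines(paste("chrS", format(config$genome_size, scientific = FALSE),
                     sep = "\t"), file.path(outdir, "chrom.sizes"))
    writeLines(paste(ann$islands$chrom,
                     format(ann$islands$start, scientific = FALSE, trim = TRUE),
                     format(ann$islands$end, scientific = FALSE, trim = TRUE),
                     sep = "\t"), file.path(outdir, "cpg_islands.bed"))
    for (tc in tracks) {
      write_coverage(cov[[tc]], file.path(outdir, paste0(tc, ".bedgraph")))
    }
    expr_tab <- data.frame(gene_id = rownames(expr$counts), expr$counts,
                           check.names = FALSE)
    write_record_table(expr_tab, file.path(outdir, "expression_counts.tsv"))
    write_record_table(scrna, file.path(outdir, "scrna.tsv"))
    Biostrings::writeXStringSet(promoters, file.path(outdir, "promoters.fa"))
  }
  out
}
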