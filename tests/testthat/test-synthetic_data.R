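test_that("label quotas are exact", {
  cfg <- small_config(seed = 1, n_genes = 100, fraction_marked = 0.1)
  ann <- simulate_annotation(cfg)
  expect_equal(sum(ann$truth$marked), 10L)
  cfg2 <- small_config(seed = 2, n_genes = 1000, fraction_paused = 0.3)
  ann2 <- simulate_annotation(cfg2)
  expect_equal(sum(ann2$truth$paused), 300L)
  expect_equal(sum(ann2$truth$expressed_ctrl), 500L)
  expect_equal(sum(ann2$truth$kinetic_class == "1hA"),
               round(0.05 * 1000))
})

test_that("generation is fully deterministic under a fixed seed", {
  cfg <- small_config(seed = 19, n_genes = 80)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1$truth, a2$truth)
  expect_identical(a1$genes$start, a2$genes$start)
  t1 <- simulate_coverage(a1, cfg, "H3S28ph", "aniso")
  t2 <- simulate_coverage(a2, cfg, "H3S28ph", "aniso")
  expect_identical(t1$values, t2$values)
  s1 <- as.character(simulate_promoter_sequences(a1, cfg))
  s2 <- as.character(simulate_promoter_sequences(a2, cfg))
  expect_identical(s1, s2)
  e1 <- simulate_expression_tables(a1, cfg)
  e2 <- simulate_expression_tables(a2, cfg)
  expect_identical(e1$counts, e2$counts)
})

test_that("infeasible packing and unknown labels are errors", {
  expect_error(simulate_annotation(sim_config(n_genes = 100,
                                              genome_size = 1e5)),
               "cannot place")
  cfg <- small_config(seed = 1, n_genes = 20)
  ann <- simulate_annotation(cfg)
  expect_error(simulate_coverage(ann, cfg, "H3K27ac", "ctrl"),
               "unknown track")
  expect_error(simulate_coverage(ann, cfg, "input", "mock"),
               "unknown condition")
})

test_that("zero depth produces empty tracks and counts", {
  cfg <- small_config(seed = 2, n_genes = 20, depth = 0)
  ann <- simulate_annotation(cfg)
  tr <- simulate_coverage(ann, cfg, "RNAPIIS5ph", "ctrl")
  expect_true(all(tr$values$chrS == 0))
  expect_equal(simulate_scrna(ann, cfg)$scrna_count, rep(0L, 20))
})

test_that("the mark appears only in the stimulated condition", {
  cfg <- small_config(seed = 5)
  ann <- simulate_annotation(cfg)
  ctrl <- simulate_coverage(ann, cfg, "H3S28ph", "ctrl")
  genes <- ann$genes
  prom_counts <- vapply(seq_len(nrow(genes)), function(i) {
    region_signal(ctrl, "chrS", genes$tss[i] - 500, genes$tss[i] + 500)
  }, 0)
  # expected background is depth/1000 * 1000 bp = depth tags per promoter
  expect_lt(max(prom_counts / cfg$depth), 3)
  calls <- call_marked_genes(ctrl, simulate_coverage(ann, cfg, "input",
                                                     "ctrl"), genes)
  expect_equal(sum(calls$marked), 0L)
})

test_that("expression tables encode the kinetic structure", {
  cfg <- small_config(seed = 8, n_genes = 400)
  ann <- simulate_annotation(cfg)
  expr <- simulate_expression_tables(ann, cfg)
  truth <- ann$truth
  # silent genes stay below log2 RPKM 0 in the control sample
  silent <- !truth$expressed_ctrl
  expect_true(all(log2(expr$rpkm[silent, "t0_ctrl"] +
                         .Machine$double.eps) < 0))
  de1 <- call_differential(expr$counts[, "t0_ctrl"],
                           expr$counts[, "t1_ctrl"],
                           expr$lib_sizes[["t0_ctrl"]],
                           expr$lib_sizes[["t1_ctrl"]])
  de3 <- call_differential(expr$counts[, "t0_ctrl"],
                           expr$counts[, "t3_ctrl"],
                           expr$lib_sizes[["t0_ctrl"]],
                           expr$lib_sizes[["t3_ctrl"]])
  g3 <- truth$kinetic_class == "3hA"
  expect_lt(mean(de1$fold[g3]), 1.5)  # no induction yet at 1 h
  expect_gte(mean(de3$fold[g3] >= 2), 0.95)
})

test_that("scRNA counts separate paused from unpaused genes", {
  cfg <- small_config(seed = 4)
  ann <- simulate_annotation(cfg)
  sc <- simulate_scrna(ann, cfg)
  present <- scrna_present(sc$scrna_count)
  expect_gte(mean(present[ann$truth$paused]), 0.95)
  expect_gte(mean(!present[!ann$truth$paused]), 0.95)
})

test_that("promoter sequences classify back to their generating class", {
  cfg <- small_config(seed = 6)
  ann <- simulate_annotation(cfg)
  seqs <- simulate_promoter_sequences(ann, cfg)
  expect_equal(unique(Biostrings::width(seqs)), 1000L)
  cls <- classify_promoters(seqs)
  expect_gte(mean(cls$cpg_class == ann$truth$cpg_class), 0.98)
})

test_that("the dataset writer emits a readable bundle", {
  cfg <- small_config(seed = 2, n_genes = 40)
  outdir <- tempfile("simout")
  sim <- simulate_dataset(cfg, tracks = c("H3S28ph_aniso", "input_ctrl"),
                          outdir = outdir)
  expect_true(all(file.exists(file.path(outdir,
    c("genes.bed", "truth.tsv", "chrom.sizes", "cpg_islands.bed",
      "H3S28ph_aniso.bedgraph", "expression_counts.tsv", "scrna.tsv",
      "promoters.fa")))))
  genes <- load_gene_models(file.path(outdir, "genes.bed"))
  expect_equal(genes$gene_id, sim$genes$gene_id)
  reread <- load_coverage(file.path(outdir, "H3S28ph_aniso.bedgraph"),
                          file.path(outdir, "chrom.sizes"), bin = cfg$bin)
  expect_equal(reread$values$chrS, sim$tracks$H3S28ph_aniso$values$chrS,
               tolerance = 1e-9)
  truth <- read_record_table(file.path(outdir, "truth.tsv"))
  expect_equal(truth$marked, sim$truth$marked)
})
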