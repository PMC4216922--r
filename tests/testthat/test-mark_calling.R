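test_that("no chip signal or chip identical to background yields no calls", {
  g <- toy_genes(c(5000, 12000), c(9000, 16000), c("+", "-"))
  bg <- uniform_track(0.1, size = 20000)
  zero <- vector_track(numeric(20000), library_size = 1e6)
  calls <- call_marked_genes(zero, bg, g)
  expect_false(any(calls$marked))
  null <- call_marked_genes(bg, bg, g)
  expect_false(any(null$marked))
  expect_true(all(abs(null$fold_enrichment - 1) < 0.05))
})

test_that("marked-gene recovery on a small simulation beats the gates", {
  cfg <- small_config(seed = 21)
  ann <- simulate_annotation(cfg)
  chip <- simulate_coverage(ann, cfg, "H3S28ph", "aniso")
  input <- simulate_coverage(ann, cfg, "input", "ctrl")
  calls <- call_marked_genes(chip, input, ann$genes)
  tp <- sum(calls$marked & ann$truth$marked)
  expect_gte(tp / sum(ann$truth$marked), 0.9)
  expect_lte(1 - tp / max(1, sum(calls$marked)), 0.1)
})

test_that("q-values are monotone in p-value rank", {
  set.seed(2)
  p <- runif(200)^2
  q <- adjust_pvalues(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("null chip/background p-values are approximately calibrated", {
  # deep background: expected counts are nearly noise-free, so the
  # fraction of genes at p <= alpha should approach alpha from below
  cfg <- small_config(seed = 31, n_genes = 1000)
  ann <- simulate_annotation(cfg)
  chip <- simulate_coverage(ann, cfg, "input", "ctrl")
  deep_cfg <- small_config(seed = 77, n_genes = 1000, depth = 1e4)
  deep_bg <- simulate_coverage(simulate_annotation(deep_cfg), deep_cfg,
                               "input", "aniso")
  calls <- call_marked_genes(chip, deep_bg, ann$genes)
  alpha <- 0.05
  n <- nrow(calls)
  expect_lte(abs(sum(calls$p <= alpha) - alpha * n), 2 * sqrt(alpha * n) + 1)
})

test_that("region features are assigned by midpoint with precedence", {
  ex <- list(cbind(start = c(10000, 12000, 15000),
                   end = c(10500, 13000, 16000)))
  g <- gene_models("g1", "chr1", 10000, 16000, "+", exons = ex,
                   thick_start = 10200, thick_end = 15600)
  fmap <- build_feature_map(g, c(chr1 = 100000))
  regions <- data.frame(
    chrom = "chr1",
    start = c(9550, 12400, 50000, 10000, 11000, 15700),
    end = c(9650, 12600, 50200, 10200, 11200, 15900))
  expect_equal(assign_region_feature(regions, fmap),
               c("promoter", "cds", "intergenic", "utr5", "intron", "utr3"))
  expect_equal(sum(fmap$fractions), 1)
})

test_that("feature enrichment reproduces closed-form binomial tails", {
  g <- gene_models("g1", "chr1", 1000, 2000, "+")
  fmap <- build_feature_map(g, c(chr1 = 100000))
  expect_equal(unname(fmap$fractions["promoter"]), 0.01)
  at_prom <- data.frame(chrom = "chr1", start = rep(400, 50),
                        end = rep(500, 50))
  fe <- feature_enrichment(at_prom, fmap)
  expect_equal(fe$p[fe$feature == "promoter"], 0.01^50, tolerance = 1e-10)
  expect_equal(fe$n_regions_in_feature[fe$feature == "promoter"], 50L)
  expect_equal(nrow(feature_enrichment(at_prom[0, ], fmap)), 0L)
})

test_that("regions proportional to the background give unit folds", {
  # genome of 4 kb: promoter 1 kb, gene body (all CDS) 1 kb, intergenic 2 kb
  g <- gene_models("g1", "chr1", 1000, 2000, "+")
  fmap <- build_feature_map(g, c(chr1 = 4000))
  regions <- data.frame(chrom = "chr1",
                        start = c(100, 1400, 2500, 3400),
                        end = c(200, 1500, 2600, 3500))
  fe <- feature_enrichment(regions, fmap)
  got <- fe[fe$n_regions_in_feature > 0, ]
  expect_equal(got$fold, rep(1, nrow(got)))
})

test_that("8 of 10 regions in a 0.2 background feature match the tail sum", {
  g <- gene_models("g1", "chr1", 1000, 2000, "+")
  fmap <- build_feature_map(g, c(chr1 = 5000)) # promoter fraction 0.2
  regions <- data.frame(chrom = "chr1",
                        start = c(rep(400, 8), 3000, 3500),
                        end = c(rep(500, 8), 3100, 3600))
  fe <- feature_enrichment(regions, fmap)
  expect_equal(fe$p[fe$feature == "promoter"], binom_tail_bf(8, 10, 0.2),
               tolerance = 1e-12)
})

test_that("CpG-island overlap counts any shared base", {
  regions <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                        end = c(50, 150, 250))
  all_islands <- data.frame(chrom = "chr1", start = 0, end = 1000)
  expect_equal(cpg_island_overlap(regions, all_islands), 1)
  expect_equal(cpg_island_overlap(regions, all_islands[0, ]), 0)
  two <- data.frame(chrom = "chr1", start = c(49, 240), end = c(60, 260))
  expect_equal(cpg_island_overlap(regions, two), 2 / 3)
})
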