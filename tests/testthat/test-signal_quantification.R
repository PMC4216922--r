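test_that("region signal sums per-base values with edge clipping", {
  tr <- uniform_track(2, size = 10000)
  expect_equal(region_signal(tr, "chr1", 500, 600), 200)
  expect_equal(region_signal(vector_track(numeric(100)), "chr1", 10, 60), 0)
  expect_equal(region_signal(tr, "chr1", 9950, 10050), 100)   # clipped half
  expect_error(region_signal(tr, "chr1", 9950, 10050, clip = FALSE),
               "outside chromosome")
  expect_error(region_signal(tr, "chrX", 0, 10), "unknown chromosome")
})

test_that("rpkm is definitional", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(25, 4000, 2e6), 3.125)
  expect_error(rpkm(10, 1000, 0), "library_size")
})

test_that("TSS fold changes behave under identity, scaling and hand input", {
  g <- toy_genes(c(2000, 12000), c(8000, 18000), c("+", "-"),
                 chrom = "chr1")
  tr <- uniform_track(1, size = 20000)
  same <- tss_fold_change(tr, tr, g)
  expect_equal(same$log2fc, c(0, 0))
  # doubled signal at equal library sizes doubles RPKM
  tr2 <- uniform_track(2, size = 20000, library_size = tr$library_size)
  tr1 <- uniform_track(1, size = 20000, library_size = tr$library_size)
  expect_equal(tss_fold_change(tr2, tr1, g, pseudo_rpkm = 0)$log2fc,
               c(1, 1))
  # 5 vs 40 tags in the window, equal libraries, no pseudocount -> log2 8
  v_ctrl <- numeric(20000); v_ctrl[2001:2005] <- 1
  v_treat <- numeric(20000); v_treat[2001:2040] <- 1
  fc <- tss_fold_change(vector_track(v_treat, library_size = 1e6),
                        vector_track(v_ctrl, library_size = 1e6),
                        g[1, ], pseudo_rpkm = 0)
  expect_equal(fc$log2fc, 3)
})

test_that("anchored profiles are flat for uniform coverage and localise deltas", {
  g <- toy_genes(c(5000, 14000), c(9000, 18000), c("+", "-"))
  tr <- uniform_track(3, size = 20000)
  prof <- anchored_profile(tr, g, "tss", flank_bp = 2000, bin_bp = 25)
  expect_equal(length(unique(prof$mean_density)), 1L)
  # all tags in the 25 bp bin containing the TSS
  v <- numeric(20000); v[5001:5025] <- 2
  dp <- anchored_profile(vector_track(v), g[1, ], "tss",
                         flank_bp = 2000, bin_bp = 25)
  expect_equal(sum(dp$mean_density > 0), 1L)
  expect_equal(dp$offset[dp$mean_density > 0], 0)
})

test_that("minus-strand genes are oriented so downstream is to the right", {
  # minus-strand gene, tags 100 bp downstream of its TSS (genomic tss-100)
  g <- toy_genes(14000, 18000, "-")
  tss <- 17999
  v <- numeric(20000); v[(tss - 100 + 1):(tss - 76 + 1)] <- 1
  prof <- anchored_profile(vector_track(v), g, "tss",
                           flank_bp = 2000, bin_bp = 25)
  peak <- prof$offset[which.max(prof$mean_density)]
  expect_gte(peak, 75)
  expect_lte(peak, 100)
})

test_that("scaled-body profiles are flat, length-invariant and capture steps", {
  tr <- uniform_track(2, size = 40000)
  g <- toy_genes(c(5000, 20000), c(6000, 30000), c("+", "+"))
  prof <- scaled_body_profile(tr, g)
  expect_equal(length(unique(prof$mean_density)), 1L)
  # identical per-bp density, very different lengths: identical body bins
  p1 <- scaled_body_profile(tr, g[1, ])
  p2 <- scaled_body_profile(tr, g[2, ])
  expect_equal(p1$mean_density[p1$segment == "body"],
               p2$mean_density[p2$segment == "body"])
  # density 2c over the first half of the body, c over the second
  v <- rep(1, 40000); v[10001:11000] <- 2
  gs <- toy_genes(10000, 12000, "+")
  sp <- scaled_body_profile(vector_track(v), gs)
  body <- sp$mean_density[sp$segment == "body"]
  expect_equal(body[1:50] / body[51:100], rep(2, 50))
  mixed <- toy_genes(c(100, 5000), c(150, 6000), c("+", "+"))
  expect_warning(short <- scaled_body_profile(tr, mixed, n_bins = 100),
                 "excluded")
  expect_equal(unique(short$n_genes), 1L)
})

test_that("profiles and rpkm are invariant to joint track rescaling", {
  set.seed(8)
  v <- as.numeric(rpois(20000, 2))
  g <- toy_genes(c(5000, 12000), c(9000, 16000), c("+", "-"))
  t1 <- vector_track(v)
  t5 <- vector_track(5 * v, library_size = 5 * t1$library_size)
  expect_equal(anchored_profile(t5, g, "tss"), anchored_profile(t1, g, "tss"))
  expect_equal(scaled_body_profile(t5, g), scaled_body_profile(t1, g))
  expect_equal(rpkm(region_signal(t5, "chr1", 5000, 6000), 1000, t5$library_size),
               rpkm(region_signal(t1, "chr1", 5000, 6000), 1000, t1$library_size))
})

test_that("binned and per-base quantification agree on aligned windows", {
  set.seed(10)
  v <- as.numeric(rpois(2000, 4))
  t_base <- vector_track(v)
  binned <- tapply(v, rep(1:80, each = 25), sum)
  t_bin <- coverage_track(list(chr1 = as.numeric(binned)), c(chr1 = 2000),
                          bin = 25)
  expect_equal(region_signal(t_bin, "chr1", 250, 1000),
               region_signal(t_base, "chr1", 250, 1000))
})

test_that("rank correlation matches midrank examples and rejects constants", {
  expect_equal(rank_correlation(1:10, 1:10 * 2), 1)
  expect_equal(rank_correlation(1:10, -(1:10)), -1)
  expect_equal(rank_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(rank_correlation(rep(1, 5), 1:5), "constant")
})
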