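test_that("BED gene models get strand-aware TSS/TES and preserve order", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t600\tg1\t0\t+",
               "chr1\t1000\t1500\tg2\t0\t-"), bed)
  g <- load_gene_models(bed, format = "bed")
  expect_equal(g$gene_id, c("g1", "g2"))
  expect_equal(g$tss, c(100, 1499))
  expect_equal(g$tes, c(599, 1000))
})

test_that("duplicate gene identifiers and malformed BED lines are rejected", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t600\tg1\t0\t+",
               "chr1\t700\t900\tg1\t0\t+"), bed)
  expect_error(load_gene_models(bed), "duplicate gene_id")
  writeLines(c("chr1\t100\t600\tg1\t0\t+",
               "chr1\t700"), bed)
  expect_error(load_gene_models(bed), "line 2")
  writeLines("chr1\t600\t100\tg1\t0\t+", bed)
  expect_error(load_gene_models(bed), "start")
})

test_that("1-based inclusive TSV maps to the same interval as BED", {
  bed <- tempfile(fileext = ".bed")
  tsv <- tempfile(fileext = ".tsv")
  writeLines("chr1\t100\t600\tg1\t0\t+", bed)
  writeLines(c("gene_id\tchrom\tstart\tend\tstrand",
               "g1\tchr1\t101\t600\t+"), tsv)
  gb <- load_gene_models(bed, "bed")
  gt <- load_gene_models(tsv, "tsv")
  expect_equal(gb$start, gt$start)
  expect_equal(gb$end, gt$end)
  expect_equal(gb$tss, gt$tss)
})

test_that("BED12 exon and CDS structure round-trips through the writer", {
  ex <- list(cbind(start = c(1000, 2000, 3500), end = c(1400, 2600, 4000)))
  g <- gene_models("g1", "chr1", 1000, 4000, "+", exons = ex,
                   thick_start = 1200, thick_end = 3800)
  bed <- tempfile(fileext = ".bed")
  write_gene_models(g, bed)
  g2 <- load_gene_models(bed, "bed")
  expect_equal(g2$start, g$start)
  expect_equal(unname(g2$exons[[1]]), unname(g$exons[[1]]))
  expect_equal(g2$thick_start, 1200)
  expect_equal(g2$thick_end, 3800)
})

test_that("bedGraph expands per base with zeros over uncovered bases", {
  bg <- tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t10\t2.0", bg)
  tr <- load_coverage(bg, c(chr1 = 20))
  expect_equal(tr$values$chr1, c(rep(2, 10), rep(0, 10)))
  expect_equal(tr$library_size, 20)
})

test_that("empty bedGraph yields an all-zero track", {
  bg <- tempfile(fileext = ".bedgraph")
  writeLines(character(0), bg)
  tr <- load_coverage(bg, c(chr1 = 50))
  expect_true(all(tr$values$chr1 == 0))
  expect_equal(tr$library_size, 0)
})

test_that("invalid bedGraph input is rejected with informative errors", {
  bg <- tempfile(fileext = ".bedgraph")
  writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t1"), bg)
  expect_error(load_coverage(bg, c(chr1 = 20)), "overlapping")
  writeLines("chr1\t10\t30\t1", bg)
  expect_error(load_coverage(bg, c(chr1 = 20)), "beyond")
  writeLines("chr1\t0\t10\t-1", bg)
  expect_error(load_coverage(bg, c(chr1 = 20)), "negative")
  writeLines("chr2\t0\t10\t1", bg)
  expect_error(load_coverage(bg, c(chr1 = 20)), "unknown chromosome")
})

test_that("coverage tracks round-trip through bedGraph at both resolutions", {
  set.seed(42)
  for (bin in c(1L, 25L)) {
    sz <- 1010
    nb <- ceiling(sz / bin)
    v <- as.numeric(rpois(nb, 3))
    tr <- coverage_track(list(chr1 = v), c(chr1 = sz), bin = bin)
    path <- tempfile(fileext = ".bedgraph")
    write_coverage(tr, path)
    tr2 <- load_coverage(path, c(chr1 = sz), bin = bin)
    expect_equal(tr2$values$chr1, tr$values$chr1, tolerance = 1e-12)
    expect_equal(tr2$library_size, tr$library_size, tolerance = 1e-12)
  }
})

test_that("record tables round-trip and keep the expected shape", {
  rec <- data.frame(gene_id = c("g1", "g2", "g3"),
                    pi_ctrl = c(5.5, 1.2, 0.8),
                    scrna_present = c(TRUE, FALSE, TRUE),
                    group = c("IIA", "III", "I"),
                    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_record_table(rec, path)
  expect_length(readLines(path), 4L)
  expect_equal(read_record_table(path), rec)
  write_record_table(rec[0, ], path)
  expect_equal(nrow(read_record_table(path)), 0L)
})
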