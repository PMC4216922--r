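# Fixture builders shared across the suite. All fixtures are constructed
# in code; nothing is read from disk except files the tests write first.

# A compact simulation that keeps the default statistical structure.
small_config <- function(seed = 3, n_genes = 300, ...) {
  sim_config(n_genes = n_genes, genome_size = 2e4 * n_genes + 1e6,
             seed = seed, ...)
}

# Uniform per-base (or binned) track: `density` tags per bp everywhere.
uniform_track <- function(density, size = 10000, chrom = "chr1", bin = 1,
                          library_size = NULL) {
  nb <- ceiling(size / bin)
  vals <- rep(density * bin, nb)
  if (nb * bin > size) vals[nb] <- density * (size - (nb - 1) * bin)
  coverage_track(stats::setNames(list(vals), chrom),
                 stats::setNames(size, chrom), bin = bin,
                 library_size = library_size)
}

# Track from an explicit per-base vector.
vector_track <- function(v, chrom = "chr1", library_size = NULL) {
  coverage_track(stats::setNames(list(v), chrom),
                 stats::setNames(length(v), chrom), bin = 1,
                 library_size = library_size)
}

# One or more simple genes on a shared chromosome.
toy_genes <- function(start, end, strand, chrom = "chr1",
                      gene_id = sprintf("g%d", seq_along(start))) {
  gene_models(gene_id, chrom, start, end, strand)
}
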