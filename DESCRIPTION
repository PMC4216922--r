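Package: chromstress
Title: Stress-Induced Histone Phosphorylation, RNAPII Pausing, and
    Induction Kinetics from ChIP-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative gene-level analysis of a stimulus-induced histone
    mark (H3S28 phosphorylation) together with RNA polymerase II
    promoter-proximal pausing, short-capped RNA evidence, CpG promoter
    classes, and induction kinetics. Provides readers for BED/bedGraph/TSV
    inputs, window and metagene signal quantification, Poisson gene-level
    enrichment calling with FDR control, pausing-index classification of
    induced genes into regulatory groups, CpG observed/expected promoter
    classing, the overlap and distribution tests used throughout the
    analysis, and a fully seeded synthetic-data generator with ground-truth
    labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
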