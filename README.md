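# chromstress

Integrative gene-level analysis of a stress-induced histone mark
(H3S28 phosphorylation) together with RNA polymerase II
promoter-proximal pausing, short-capped RNA (scRNA) evidence, promoter
CpG classes, and transcriptional induction kinetics. The package is
aimed at chromatin and regulatory-genomics analysts who want the whole
inference chain — from bedGraph coverage and count tables to the final
overlap statistics — as tested, seed-reproducible R functions, plus a
synthetic-data generator with ground-truth labels to validate every
step.

## What it computes

* **Marked genes** — for each gene, ChIP tags in a strand-oriented
  promoter window (TSS ± 500 bp) are tested against a background track:
  expected count λ = background × library ratio + 1, fold enrichment
  c/λ, Poisson upper-tail p = P(X ≥ c | λ), BH (or Hochberg) q-values.
  A gene is marked when q ≤ 0.05 and fold ≥ 5.
* **Pausing index** — PI = density(TSS −50..+300) / density(+300..TES)
  for RNAPII S5ph; PI > 2 with scRNA present defines a paused gene, and
  up-regulated genes are classified into the four regulatory groups
  (I, IIA, IIB, III) from their basal and stimulated PI.
* **Differential expression and kinetics** — library-size-normalized
  fold changes with a conditional binomial exact test; 1hA/3hA/6hA
  kinetic classes from the literal time-point gates; reduced-induction
  calls under kinase inhibition.
* **Promoter CpG classes** — sliding-window CpG observed/expected and GC
  content classify promoters as HCP/ICP/LCP.
* **Set statistics** — log-space upper-tail hypergeometric overlaps,
  Fisher 2×k exact tests, Mann–Whitney U, one-sided binomial feature
  enrichment, χ² class-distribution tests, BH/Hochberg correction.
* **Signal profiling** — RPKM window quantification, TSS/TES-anchored
  and scaled-body metagene profiles with expression stratification.
* **Synthetic data** — `simulate_dataset()` generates annotation,
  coverage tracks, expression/scRNA tables and promoter sequences with
  per-gene ground truth, so recovery (sensitivity, FDR, group/class
  agreement) is measurable.

## Worked example

```r
library(chromstress)

# published-scale checks from their integer inputs
worked_examples()
#>                           check     computed
#> 1 marked_up_overlap_hypergeom_p 3.888403e-55
#> 2             marked_up_percent 4.900000e+01
#> 3          expressed_up_percent 9.200000e+01

# full pipeline on the reference simulation (2,000 genes, depth 100)
report <- run_pipeline(sim_config(seed = 7))
report
#> chromstress pipeline report
#>   statistics:
#>     n_marked                   240
#>     n_up_1h                    102
#>     marked_up_overlap          12
#>     marked_up_pct              12
#>     expressed_up_pct           50
#>     hypergeometric_p           0.578
#>     group_fisher_p             0.3657
#>     cpg_chisq_p                0.3437
#>     cpg_island_overlap         0.475
#>     acetylation_mw_p           0.1693
#>     spearman_s5ph_expression   0.8514
#>   ground-truth recovery:
#>     marked_sensitivity         1.0000
#>     marked_fdr                 0.0000
#>     group_accuracy             1.0000
#>     kinetic_agreement          0.9915
#>     cpg_agreement              0.9985
```

The first block recomputes the headline published-scale numbers from
their integer inputs: an upper-tail hypergeometric p of 3.9 × 10⁻⁵⁵ for
the overlap of 2,480 marked genes with 284 up-regulated genes (overlap
138) in a 21,608-gene universe, and the two derived percentages (49% of
up-regulated genes marked; 92% basally expressed). In the simulation
report, mark status and induction are independent by construction, so
the association statistics sit at their null values while the recovery
block shows the pipeline retrieving the generator's ground-truth labels:
all 240 marked genes are recalled without false positives, every
up-regulated gene lands in its true regulatory group, and kinetic and
CpG class agreement are ≥ 0.99.

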