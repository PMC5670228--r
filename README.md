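# xreact

Allele-specific single-cell analysis of paternal X-chromosome
reactivation in the mouse blastocyst.

## The problem

In female mouse pre-implantation embryos, imprinted X-chromosome
inactivation silences the paternal X (Xp) everywhere — and the inner
cell mass (ICM) then reverses it, gene by gene, on its way to the
epiblast. Single-cell RNA-seq of hybrid (C57BL/6J × CAST/EiJ) embryos
makes this process measurable: strain SNPs assign each read to its
parental allele, so every gene in every cell gets an **allelic ratio**

    r = paternal reads / (paternal + maternal reads)

after two informativity gates (≥ 5 allele-assigned reads per SNP,
≥ 8 per gene). `xreact` is a tidyverse-style R package implementing the
full analysis chain for researchers studying X-reactivation kinetics:

* SNP-to-gene allelic aggregation, allelic-state calls
  (monoallelic ≤ 0.15 / ≥ 0.85, biallelic in between);
* the 3′-capped expression measure **RPRT** (reads per kb of
  retrotranscribed length, capped at 3 kb, per million mapped reads)
  with expressed (> 1) / well-expressed (> 4) filters;
* lineage assignment of blastocyst cells (E3.5 TE, pre-lineage E3.5
  ICM, E4.0 PrE, E4.0 Epi) by Pearson–Ward clustering on lineage
  markers;
* a rule-based classifier of **reactivation timing** per X-linked gene
  — early (biallelic already in the E3.5 ICM), late (only in the E4.0
  epiblast), very late (still silenced), escapee (never silenced) —
  from gene-by-group mean allelic ratios under 25%-of-cells inclusion
  rules, with a strict > 0.20 reactivation threshold;
* downstream statistics: per-cell reactivation percentages, a
  Pearson + Benjamini–Hochberg correlation screen, the Xist
  anti-correlation test (Spearman, exact permutation p at small n),
  allele-resolved H3K27me3/H3K4me3 enrichment in 5-kb TSS windows with
  Wilcoxon class contrasts, and TF association-score aggregation with
  Kruskal–Wallis / Dunn post hoc tests;
* a seeded synthetic-data generator with known ground truth (latent
  timing classes, lineages, Xist suppression, binomial allele sampling
  with expression-dependent dropout) that exercises the entire pipeline
  without external data.

See `vignettes/xp-reactivation-methods.Rmd` for the model, every
threshold with its rationale, and the generator's assumptions.

## Worked example

```r
library(xreact)

bundle <- simulate_bundle(sim_config(seed = 1))  # 100 X-linked genes, 70 cells
res <- run_pipeline(bundle)
print(res)
#> xreact pipeline results
#>   cells: 70 | genes classified: 100
#>   timing classes:
#>
#>     early   escapee      late     other very_late
#>        20        20        39         1        20
#>   Xist anti-correlation: Spearman rho = -0.464, p = 0.0003575 (spearman_t_approximation, n = 55)

head(res$timing[, c("gene_id", "timing", "rule_fired")], 4)
#> # A tibble: 4 × 3
#>   gene_id timing    rule_fired
#>   <chr>   <chr>     <chr>
#> 1 Xg001   very_late no_group_reactivated
#> 2 Xg002   late      epi_reactivated_only
#> 3 Xg003   early     te_silenced_icm_reactivated
#> 4 Xg004   late      epi_reactivated_only
```

Each X-linked gene receives exactly one timing class together with the
rule that fired (`other` is the imprinted Xist). The Spearman rho of
−0.46 (p ≈ 4 × 10⁻⁴ over the 55 ICM-derived cells) quantifies the
anti-correlation between a cell's Xist expression and the percentage of
its X-linked genes already reactivated. `autoplot()` methods draw the
gene-by-group ratio heatmap (maternal red → paternal blue) and PCA
plots; `generics::tidy()` / `glance()` extract test results as tibbles.

On this bundle the classifier recovers 100/100 true timing classes and
all 40 E4.0 cells are assigned to their true lineage; the truth tables
live in `bundle$truth`.

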