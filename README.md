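# laasp

Early-life environmental exposures (BPA, TBT, TCDD, PM2.5, ...) can durably
reprogram the liver transcriptome and epigenome. A recurring observation in
longitudinal mouse studies is that the genes hit by very different toxicants
converge on the set of genes that normally change expression as the liver
ages — *liver aging-associated plasticity* (LAAsP) genes — and that the
exposures frequently *attenuate* those genes' normal aging trajectories:
genes that should rise with age stay low, genes that should fall stay high.
`laasp` implements that analysis as a tested, seed-reproducible R pipeline
for computational biologists working with gene-level count matrices,
differential histone-mark peaks, and enhancer-gene link catalogs. Because
the consortium-scale raw data cannot be shipped, the package includes a
first-class synthetic multi-omic study generator with planted ground truth,
so every stage has a recovery target.

## What it computes

- **Differential calls.** Genes (`call_degs()`, Welch t-test on
  log2 CPM with BH FDR) and tiled histone-mark windows (`call_deps()`,
  library-size-normalized G-test with adjacent-window merging), both called
  at the study rule *q* < 0.05 and linear fold change > 1.5, plus a
  Jensen–Shannon signal-quality distance (`jsd_qc()`).
- **Trajectory classification.** For a gene in both an exposure signature
  and the aging signature, with aging direction *a* ∈ {up, down} and
  exposure direction *e*: the call is **attenuated** if *e* ≠ *a* and
  **accelerated** if *e* = *a* (`classify_trajectories()`), with overlap
  percentages through `overlap_fraction()` (nearest-integer and floor
  variants), sex partitions (`sex_partition()`), and exact multi-set Venn
  counts (`core_overlap()`).
- **Regulatory mapping.** Strand-aware promoter windows TSS ± 3 kb
  (`promoter_windows()`), merging of adjacent catalog enhancers into
  *anchors* carrying the union of their gene links (`build_anchors()`),
  ≥ 1 bp peak-to-gene assignment (`assign_peaks()`), and
  expression/mark concordance — a peak is concordant when an active mark
  moves with expression or a repressive mark against it — partitioned into
  promoter-only / enhancer-only / both / neither per gene
  (`classify_concordance()`).
- **Enrichment.** Hypergeometric ORA (`ora()`), preranked GSEA with the
  weighted Kolmogorov–Smirnov running sum, gene-set permutation null and
  sign-matched NES (`gsea_preranked()`), a 10,000-permutation normal-fit
  test for shared-pathway overlap between exposures
  (`pathway_overlap_test()`), and the shared-pathway network
  (`build_overlap_network()`).
- **Signature activity.** Per-gene z-scoring across samples
  (`zscore_matrix()`), the summed z-score statistic
  *S(sample) = Σ z(up genes) − Σ z(down genes)* (`signature_score()`),
  Pearson signature–signature correlation (`score_correlation()`),
  mouse→human homolog mapping (`map_homologs()`), and ordinal
  disease-severity association (`severity_association()`).
- **Synthetic study.** `simulate_study()` plants negative-binomial aging
  and exposure effects (with configurable attenuated/accelerated
  fractions), Poisson histone-mark windows with a configurable
  expression-concordance rate, and an enhancer catalog averaging ~8 links
  per gene; `simulate_cohort()` builds a severity-graded human-like
  cohort. `run_study()` wires everything end to end and writes a
  machine-readable report.

Results come back as tibbles; fitted objects have `tidy()` / `glance()`
methods and `autoplot()` / `plot_*()` figures.

## Worked example

```r
library(laasp)

cfg <- run_config(sim = simulation_config(
  n_genes = 800, samples_per_group = 5,
  exposures = c("vehicle", "TBT", "TCDD"), seed = 5))
report <- run_study(cfg)

report$trajectory_summary
#> # A tibble: 2 × 9
#>   exposure n_signature n_overlap percent_exact percent n_attenuated n_accelerated attenuated_share accelerated_share
#> 1 TBT              220       114          51.8      52          106             8            0.930            0.0702
#> 2 TCDD             222       116          52.3      52          108             8            0.931            0.0690
```

Just over half of each exposure signature consists of aging-plasticity
genes (52%), and ~93% of those shared genes move *against* their normal
aging direction — the planted attenuation (the generator planted 150
attenuated vs 10 accelerated genes among the 160 aging genes available,
i.e. a 0.94 attenuated share, recovered here as 0.93).

```r
report$concordance$summary
#> # A tibble: 1 × 8
#>   n_genes promoter_only enhancer_only  both neither percent_concordant_exact percent_concordant percent_concordant_floor
#> 1     127            40            35    46       6                     95.3                 95                       95
```

95% of differential genes show a direction-concordant histone-mark change
in at least one regulatory element, split across promoters, linked
enhancer anchors, or both.

```r
report$score_correlation
#> # A tibble: 3 × 4
#>   signature  aging    TBT   TCDD
#> 1 aging      1     -0.999 -0.999
#> 2 TBT       -0.999  1      0.997
#> 3 TCDD      -0.999  0.997  1
tidy(report$severity_association)
#> # A tibble: 1 × 3
#>       r   p_value     n
#> 1 0.997 4.18e-220   200
```

On the simulated severity cohort the exposure signatures are strongly
anti-correlated with the aging signature (r ≈ −1, the summed z-score
fingerprint of attenuation), and aging-signature activity tracks disease
severity almost perfectly.

Single operations work standalone on plain tables, e.g. the percentage a
186-gene overlap represents of a 2582-gene signature:

```r
overlap_fraction(186, 2582)
#> # A tibble: 1 × 5
#>   n_overlap n_total percent_exact percent percent_floor
#> 1       186    2582          7.20       7             7
```

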