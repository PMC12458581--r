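---
title: "Methods: aging-trajectory plasticity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aging-trajectory plasticity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laasp)
```

## The scientific model

The package analyses a longitudinal exposure study design: mice exposed to
a toxicant from pre-conception through weaning, then profiled at weaning
and in adulthood alongside vehicle controls. Three quantitative ideas sit
at its core.

**Aging-plasticity genes.** A gene that changes expression between the
young and adult vehicle groups — at BH FDR *q* < 0.05 and linear fold
change > 1.5 — retains the plasticity to change with age. The set of such
genes, split into an up and a down component, is the aging signature
against which every exposure is compared.

**Trajectory attenuation.** For a gene that is differential both under an
exposure (vs age-matched vehicle) and with age, two directions are in
play: its normal aging direction and its exposure direction. When they
disagree, the exposure has *attenuated* the gene's normal trajectory (a
gene that should rise with age is held low; one that should fall stays
high); when they agree the trajectory is *accelerated*. The classification
is a pure function of the two direction calls, so its correctness reduces
to the correctness of the differential calls upstream.

**Summed z-score signature activity.** To ask whether a signature is
"switched on" in an independent cohort, each gene is z-scored across the
cohort's samples and a sample's activity is the sum of z-scores over the
signature's up genes minus the sum over its down genes. The statistic is
linear, so per-gene affine changes of scale cancel exactly (a property the
test suite asserts), and anti-correlation between an exposure signature's
activity and the aging signature's activity is the cohort-level
fingerprint of attenuation.

On the epigenomic side, differential histone-mark peaks are mapped to
genes through two region classes: the promoter window (TSS ± 3 kb,
strand-symmetric, clipped at zero) and *enhancer anchors* — catalog
enhancers merged when they overlap or are book-ended, carrying the union
of their constituent enhancer–gene links. A peak is *concordant* with its
gene when an active mark (H3K27ac, H3K4me1, H3K4me3) moves in the gene's
expression direction or a repressive mark (H3K27me3, H3K9me3) moves
against it. Each differential gene is then categorised as having
concordant changes at the promoter only, a linked enhancer only, both, or
neither; the four categories partition the gene list by construction.
H3K9me3 is excluded from the default aging analysis (an
`include`-by-polarity-map flag restores it) because constitutive
heterochromatin is essentially static over the study interval.

## Declared stand-ins for the differential callers

The bespoke content of this package is downstream of differential calling,
so the two callers are deliberately simple, declared substitutes rather
than re-implementations of count-model fitters:

- `call_degs()` CPM-normalises, tests `log2(CPM + 0.5)` with a Welch
  two-sample t-test, and BH-adjusts. The fold change is the ratio of group
  mean CPMs with a 0.5 pseudo-count, which keeps it finite and makes it
  invert exactly under a group swap (asserted as a label-symmetry test).
- `call_deps()` pools counts per tiled window, applies a
  library-size-normalised G-test (likelihood-ratio against expected
  sharing proportional to library size), BH-adjusts across tested windows,
  and merges *strictly adjacent* significant windows of the same direction
  into one peak carrying the extreme log2 fold change. Zero-gap-only
  merging is deterministic and matches the tiling; windows empty in both
  groups are skipped.

Their adequacy is checked statistically rather than against an external
fitter: on all-null simulated counts (2,000 genes, 5 vs 5) the fraction of
*q* < 0.05 calls stays within three binomial standard deviations of the
nominal rate, and planted |log2FC| = 1 effects at 10 per group are
recovered at ≥ 80%.

## The synthetic study generator

`simulate_study()` is first-class, tested code, not a fixture. It emulates:

- **Counts.** Negative binomial with variance μ + φμ², gene baselines
  log-normal (`nb_mean_log = 5` natural-log scale, i.e. median ≈ 150
  counts), dispersion φ = 0.1 (a typical bulk RNA-seq value), and
  per-sample log-normal library-size factors (σ = 0.2) so CPM
  normalisation is actually exercised.
- **Design.** Two age groups (weaning, adulthood) crossed with exposure
  arms; exposure effects are applied at the adult age only, mirroring the
  adult-timepoint exposure comparisons. Defaults: 2,000 genes, 6
  replicates per cell, arms vehicle + BPA.hi + TBT + TCDD (the three
  exposures the trajectory analyses focus on).
- **Planted structure.** 5% of genes age up and 15% down (aging in this
  interval is strongly down-dominant, roughly 20% of expressed genes
  changing), both at |log2FC| = 1.5 so planted fold changes clear the
  1.5× gate. Each arm perturbs 300 genes (the scale of a large exposure
  signature): 50% drawn from aging genes with the opposite direction
  (attenuated), 20% with the same direction (accelerated), the rest from
  null genes.
- **Peaks.** One synthetic chromosome (`chrS`), genes on alternating
  strands at 20-kb spacing, 1-kb tiling windows with Poisson counts
  (background rate 20/window). Every aging gene receives one planted
  3-window peak per mark, at its promoter or a linked enhancer, whose
  direction is concordant with expression (given mark polarity) with
  probability `concordance_rate = 0.85`.
- **Enhancer catalog.** Per-gene enhancer counts drawn so the mean number
  of linked enhancers per gene is 8, with each enhancer linking its owner
  gene and occasionally a neighbour (1–3 genes per enhancer). Enhancers
  are laid out in pairs, book-ended with probability `adjacency_rate`
  (default 0.2), so anchor merging has a planted, countable expectation.
- **Cohort.** `simulate_cohort()` assigns balanced ordinal severity
  labels and moves signature genes linearly with the severity index on a
  unit-variance noise background.

What the generator does **not** emulate: batch and litter effects,
genuine biological dispersion heterogeneity, realistic genome sequence or
peak shapes, correlated gene modules beyond the planted pathway bias, and
sex as a simulation axis (sex-specific analyses are exercised by
simulating two independent studies). Passing tests therefore demonstrate
that the pipeline recovers the structure it models — planted effect
directions, attenuation shares, concordance rates, anchor multiplicities —
not that it is robust to every artefact of real consortium data.

## Numerical and design choices

- **Coordinates** are 0-based half-open everywhere internally (BED
  convention); conversion to the 1-based closed convention used by the
  interval machinery happens only at the `GenomicRanges` boundary.
  Assignment requires ≥ 1 bp of true overlap, so an exactly abutting peak
  does not assign.
- **Anchor merging** uses `max_gap = 0` by default — only overlapping or
  book-ended enhancers merge. "Adjacent" has no stated distance in the
  source catalogs, and 0 is the conservative `bedtools merge` default; the
  parameter is exposed.
- **Rounding of printed percentages**: `overlap_fraction()` returns the
  exact percent plus nearest-integer (half away from zero) and floor
  variants, because published integer percents mix both conventions (e.g.
  2295/2582 printed as 88% is the floor of 88.9). Nothing downstream
  rounds silently.
- **Composite signatures across sexes** use the union of same-direction
  calls; genes discordant between sexes are excluded from the composite
  but remain visible in `sex_partition()`. Union (rather than
  intersection) was chosen because a plasticity gene evidenced in either
  sex is a plasticity gene; the discordant exclusion keeps the up/down
  sets disjoint.
- **Z-scoring** uses the population (divisor-*n*) standard deviation and
  maps zero-variance genes to z = 0 with a flag. The affine-invariance
  property holds under either divisor; the choice only rescales scores.
  Scores are raw sums (not means), with `n_genes_used` reported so users
  can normalise; per-cohort z-scoring is applied when several cohorts are
  compared.
- **Severity encoding** is 0..k−1 with unit spacing in the supplied
  order — the minimal assumption for "numerical values in order of
  severity". The sign of the association is stable under any strictly
  increasing re-encoding (asserted in tests); the magnitude is not, which
  is inherent to Pearson correlation on ordinal encodings.
- **GSEA details.** Hit increments are |score|^weight normalised within
  the set (weight 1 by default; weight 0 gives the classic statistic);
  ties in scores are broken by stable input order, documented because tie
  handling differs between implementations. The null permutes gene-set
  membership (not phenotype labels), NES divides ES by the mean |null ES|
  of matching sign, and the p-value is the one-sided empirical frequency
  with the +1 correction. A set covering the whole ranked list has ES
  defined as 0.
- **Pathway-overlap test.** Permutations draw pathway sets uniformly
  without replacement, matching the observed set sizes; the p-value is the
  upper tail of a normal fitted to the permutation overlaps (the test asks
  about over-sharing, so it is one-sided). Uniform sampling is used;
  size-stratified sampling within compendia would be a straightforward
  extension but is not implemented. A degenerate null (sd = 0) is flagged
  explicitly: p = 1 when the observed overlap does not exceed the constant
  null, the smallest representable double when it does.
- **Degenerate inputs.** All-zero genes stay in differential tables with
  p = 1 and an `ns` call; empty differential tables give empty signatures
  with a warning; anchors with links to genes outside the annotation keep
  the link (the catalog's gene universe may legitimately be larger).

## Problem sizes used by the test suite

The suite runs the statistical checks at sizes chosen to make their
binomial/Monte-Carlo tolerances meaningful on a single CPU: 200 random
instances (up to 500 intervals) for the anchor-merge oracle; exhaustive
hypergeometric enumeration for every universe up to 12; 10,000
permutations for the closed-form null-mean check and 500 replicates at 500
permutations each for type-I calibration; 2,000-gene simulations for
differential calibration and power; and ten seeded end-to-end pipeline
runs at 1,000 genes for attenuation-share recovery. The full suite runs in
roughly two minutes.

## Known limitations

- The differential stand-ins do not model litter as a blocking factor;
  samples are treated as exchangeable. This is flagged rather than
  guessed, since the real design nests animals within litters.
- Enhancer→gene links come exclusively from the catalog; there is no
  distance-based nearest-gene fallback, so genes absent from the catalog
  can only receive promoter assignments.
- The permutation and GSEA nulls are gene-set-based; phenotype-permutation
  GSEA is out of scope.
- A peak overlapping both the promoter and a linked enhancer of the same
  gene contributes to both region classes; both raw and per-gene
  de-duplicated views are available in the concordance records.
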