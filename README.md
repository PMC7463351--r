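# maizeUVB

Downstream transcriptomic analysis of maize landraces from three
elevational zones (lowland ≈ 600 m, midland ≈ 1,550 m, highland ≈ 2,100 m)
grown in a blocked common garden. The package asks whether genes encoding
enzymes of phenolic-compound biosynthesis — phenylpropanoid, flavonoid and
lignin pathways plus nucleotide-sugar interconversion, all contributors to
UV-B protection — are over-represented among the genes differentially
expressed between zones of origin, a pattern consistent with UV-B acting as
a selective agent along the gradient.

It is aimed at researchers who have a gene-level count matrix for a
multi-group design and want a candidate-set enrichment analysis that
controls for expression level, together with the surrounding normalization,
differential-expression and clustering stages.

## What it computes

1. **Normalization** — median-of-ratios size factors
   `s_j = median_i ( K_ij / (prod_j K_ij)^(1/n) )` over genes observed in
   every library, plus a shifted-log (`log2(x+1)`) variance-stabilizing
   transform for clustering.
2. **Differential expression** — per gene, a negative-binomial GLM
   `log mu_ij = log s_j + beta_0 + beta_block(j) + beta_zone(j)` fitted by
   IRLS with method-of-moments dispersions shrunk toward a mean-dispersion
   trend; Wald tests for the three pairwise zone contrasts; BH FDR with an
   inclusive 0.05 call threshold.
3. **Expression-matched enrichment** — candidates binned into 10
   equal-width bins of average normalized expression; sparse bins above
   3,000 counts dropped; each comparison's background (universe ∪ DE genes
   ∪ candidates) subsampled without replacement to the candidate bin
   profile by maximal-N largest-remainder quotas; the match verified by
   chi-square; and the enrichment tested with a Yates-corrected chi-square
   on the 2×2 table `[[cand_DE, DE_total], [cand_bg, bg_total]]`:
   `X² = Σ (max(0, |O − E| − 0.5))² / E`.
4. **Consensus clustering** — 1 − Spearman distances between libraries,
   average linkage, k = 18, 1,000 gene-resampling iterations (80% without
   replacement), aggregated into a co-clustering frequency matrix; plus
   1 − Pearson gene clustering and min-max row scaling for heat-map layout.
5. **Synthetic data** — a seeded negative-binomial generator for the
   45-library design (3 zones × 5 landraces × 3 blocks) with planted zone
   effects, a tunable candidate enrichment factor φ, and full ground truth,
   so every stage is testable without the original sequencing data.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_normalize.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_clustering.R
```

simulates the preset experiment (2,190 genes, φ = 4 planted candidate
enrichment) and prints, among other diagnostics:

```
planted DE highland-lowland: 127 of which candidates: 43
candidate / background planted DE prevalence:  5.39

max relative error vs true factors: 0.0534

highland-lowland  called  130 (planted  127): power 0.96, FDP 0.062

bin occupancy: 188 1 0 0 0 0 0 0 0 0
1 candidates dropped by the sparse high-expression bin filter; 189 remain
highland-lowland: matched background 1990 genes (37 out of range), match chi2 1.47e-27 p 1.000
       comparison         chi2            p background_ratio de_ratio enriched
 highland-lowland 4.033847e+01 2.135621e-10         189/1990   41/130      Yes
 highland-midland 3.419591e-04 9.852463e-01         189/1990     2/15       No
  midland-lowland 3.786512e+01 7.580842e-10         189/1990   41/135      Yes

top split vs zone:
   zone
two highland lowland midland
  1        0      15       0
  2       15       0      15
top split isolates the lowland libraries: yes
```

Reading this: the simulator planted 127 highland–lowland DE genes; the DE
stage recovered them with 96% power at a 6% realized false-discovery
proportion; the matched background reproduces the candidate expression
profile essentially exactly (match p ≈ 1); the candidate set is strongly
over-represented among DE genes (41/130 vs 189/1990, chi-square 40.3,
enriched = Yes) in the two comparisons with substantial planted signal,
while the milder highland–midland comparison (15 DE genes in this run) is
correctly not called; and the consensus tree's first division separates the 15
lowland libraries from the midland + highland group, the qualitative
pattern expected when midland expression sides with highland.

Stage outputs (DE tables, enrichment table, matched background lists,
consensus matrix/tree/labels, heat-map matrix) are written under
`results/`.

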