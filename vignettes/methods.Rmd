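---
title: "Elevational differential expression and expression-matched enrichment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elevational differential expression and expression-matched enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizeUVB)
```

## The scientific setting

maizeUVB analyzes gene-level RNA-seq counts from maize landraces collected
in three elevational zones (lowland ≈ 600 m, midland ≈ 1,550 m, highland ≈
2,100 m) and grown together in a common garden with three field blocks.
Each of the 45 libraries is one landrace in one block (three zones × five
landraces × three blocks). The central question is whether genes encoding
enzymes of phenolic-compound biosynthesis — phenylpropanoid, flavonoid and
lignin pathways plus nucleotide-sugar interconversion, all contributors to
UV-B protection — are over-represented among the genes differentially
expressed between zones, which would be consistent with UV-B irradiance
acting as a selective agent along the gradient.

The package implements four stages, each usable on its own: median-of-ratios
normalization, per-gene negative-binomial differential expression with
pairwise zone contrasts, candidate-set enrichment against an
expression-matched background, and resampling consensus clustering of
libraries. A seeded simulator reproduces the factor structure of the design
so every stage can be validated against known truth.

## Normalization

Size factors are the median, over genes observed in every library, of the
ratio of each library's count to the gene's geometric mean across libraries
(`estimate_size_factors()`). The geometric mean is computed in log space to
avoid overflow; the median is taken on the ratio scale. Genes containing any
zero are excluded from the reference set, and a matrix with no all-positive
gene is an error rather than a silent fallback.

One property worth spelling out: because the reference profile is itself a
geometric mean over libraries, multiplying one library's counts by a
constant `c` rescales *all* factors (the scaled library's by `c^((n-1)/n)`,
the others by `c^(-1/n)`). What is invariant is the *ratio* between size
factors, which changes by exactly `c`, and the normalized matrix, which
changes only by a single global constant. The test suite checks this
equivariant form rather than a naive per-column invariance, which does not
hold for any median-of-ratios implementation.

For clustering we use a shifted log transform, `log2(x + 1)`, as the
variance-stabilizing step. The downstream correlation distances depend only
on rank and linear structure, so the difference from a parametric
variance-stabilizing transform is immaterial there; the simpler transform is
monotone, maps zero to zero, and is exactly reproducible.

## Differential expression

Each gene is modeled as

$$K_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i), \qquad
\log \mu_{ij} = \log s_j + \beta_0 + \beta_{\mathrm{block}(j)} +
\beta_{\mathrm{zone}(j)},$$

with the library size factor entering as a fixed offset. The model is
deliberately additive — block is a nuisance fixed effect and no
zone-by-block interaction is fitted, mirroring the two-factor formulation
used for this design. The split-plot error structure of the field layout is
not modeled.

**Dispersion.** `estimate_dispersions()` uses method-of-moments estimates
computed within zone-by-block cells (so real zone or block differences do
not inflate them): per cell, `max(0, (var - mean) / mean^2)`, pooled across
cells with degrees-of-freedom weights. The raw estimates are then shrunk
halfway toward a mean-dispersion trend obtained by lowess smoothing of the
raw values against log mean expression. The 50/50 blend is a fixed design
choice: it stabilizes the noisy 36-df gene-wise estimates without the
empirical-Bayes machinery of the larger DE packages, and simulation tests
show the resulting Wald p-values are well calibrated (null fraction called
at FDR 0.05 is far below 0.05; Kolmogorov–Smirnov uniformity is not
rejected on null data).

**Fitting.** Each gene's GLM is fitted by iteratively reweighted least
squares with the canonical log link, a maximum of 50 iterations and a
relative deviance tolerance of 1e-8. Working weights are
`mu / (1 + alpha * mu)` (the expected information for fixed dispersion);
the linear predictor is clamped to ±30 to keep degenerate genes finite.
Genes that fail to converge, are all-zero, or produce a singular
information matrix are flagged, receive missing p-values, and are excluded
from the FDR denominator with a logged count.

**Contrasts.** The three pairwise zone comparisons are linear contrasts of
the zone coefficients from the single fit; the Wald statistic is the
contrast estimate over its standard error with a two-sided standard-normal
p-value, and log2 fold changes are the natural-log coefficients divided by
`ln 2`. Positive values mean higher expression in the first-named zone.
Because all three contrasts come from one coefficient vector, the identity
`lfc(H,L) = lfc(H,M) + lfc(M,L)` holds exactly in the estimates.

Simplifications relative to the large DE packages are intentional and
documented: no fold-change shrinkage, no outlier filtering, no independent
filtering. The package's validation surface is simulation-based recovery
(type-I error, power, realized FDR), not bit-level agreement with any
external tool. No minimal-count pre-filter is applied before testing —
only all-zero genes drop out, through the normalization reference and the
enrichment stage's explicit zero-expression removal; callers can filter
upstream if desired.

Multiple testing uses the Benjamini–Hochberg step-up rule via
`stats::p.adjust` over the non-missing p-values; the DE call threshold
(default FDR ≤ 0.05) is inclusive.

## Expression-matched enrichment

The headline statistic asks whether candidates are over-represented among
DE genes *after* removing expression level as a confounder, since candidate
genes skew toward low expression:

1. **Binning.** Candidate genes with nonzero mean normalized expression are
   placed into 10 equal-*width* bins spanning their expression range.
   "Equally sized" here means equal width, not equal occupancy: the study's
   printed edges (0.02–760.01, 760.01–1,520) are equal-width, and an 89%
   first-bin occupancy is incompatible with deciles. Intervals are
   right-open except the last.
2. **Bin filtering.** Bins whose lower edge exceeds 3,000 counts and which
   hold two or fewer candidates are dropped, and their genes leave the
   working candidate set (in the study, 179 → 175). Both the occupancy
   cutoff and the count threshold are exposed as parameters.
3. **Background assembly.** The comparison's background is the union of the
   expressed-gene universe, that comparison's DE genes, and the candidates
   themselves. Out-of-range genes (means outside the candidate bin span)
   are excluded after this augmentation.
4. **Matching.** The matched background is the largest subsample whose
   per-bin composition equals the candidate proportions: the total N is the
   largest integer with `ceiling(N * p_k)` within every bin's availability,
   per-bin quotas come from largest-remainder apportionment (deterministic
   earlier-bin tie-break), and quota genes are drawn uniformly without
   replacement under the caller's seed. This one-shot maximal-N allocation
   satisfies "same proportion per bin" deterministically — per-bin
   deviations are below 1/N — without iterative rejection.
5. **Match verification.** A two-sample chi-square on the bins ×
   {candidate, matched} table (Yates correction only when exactly two bins
   remain, matching the 2×2 convention); a match requires p > 0.95, and in
   practice p > 0.999.
6. **The enrichment test.** `yates_chi2()` forms the 2×2 table whose cells
   are the four printed numbers — candidate and total counts of the DE list
   in one row, candidate and total counts of the matched background in the
   other — and computes `sum((max(0, |O - E| - 0.5))^2 / E)` with expected
   values from the margins and an upper-tail chi-square(1) p-value. Using
   the list totals as cells (rather than margins of a partition) is
   statistically unconventional, but it is the only construction that
   reproduces the published statistics (17.94, 4.84, 4.00) from the
   published ratios; the conventional nested candidate-in/out × DE-in/out
   partition is available as `nested = TRUE`. The continuity correction is
   capped at `|O - E|` so a perfectly proportional table scores exactly 0.
   A comparison is *enriched* only when p < 0.05 **and** the candidate rate
   in the DE list exceeds the background rate — significant depletion is
   reported as not enriched.

## Consensus clustering

Libraries are clustered on variance-stabilized candidate-gene expression
with 1 − Spearman rank correlation distances and average (UPGMA) linkage.
Stability comes from resampling: each of the (default 1,000) iterations
draws 80% of the genes without replacement, re-clusters the libraries at
`k` (default 18, the study setting), and records co-membership. The
consensus matrix — the fraction of iterations in which two libraries
co-cluster; every library is present in every iteration, so the denominator
is simply the iteration count — is then clustered once more with average
linkage on 1 − consensus. Which entities the study's tool resampled is not
documented; gene (feature) resampling at 80% is standard consensus-
clustering practice and is the documented choice here, with the fraction
exposed as a parameter. Identical seeds give identical consensus matrices.

Heat-map layout for DE genes follows the published figures: normalized
counts aggregated to landrace means, rows min-max scaled to [0, 1]
(constant rows become 0.5 with a warning), and row order taken from an
average-linkage dendrogram on 1 − Pearson distances between gene profiles.

## The synthetic experiment

`simulate_experiment()` generates counts
`K_ij ~ NB(s_j * mu_i * 2^(zone_ij + block_ij), alpha)` under the
45-library design. Choices that matter, with defaults:

- **Baselines.** Background gene means are log-normal (meanlog 4, sdlog 2,
  i.e. median ≈ 55 normalized counts with a heavy right tail spanning the
  10^-1–10^5 range typical of RNA-seq). Candidates draw from meanlog 2.5
  with the same spread — deliberately lower, so that most candidates fall
  in the lowest expression bins and the expression-matching step does real
  work; with an expression-neutral candidate set the matched and unmatched
  analyses would coincide and the matching code would be untested.
- **Differential expression.** A background gene is DE with probability
  0.05; candidates with probability `min(1, phi * 0.05)`, `phi` being the
  planted enrichment factor. Planted log2 fold changes are normal with SD
  1.5, truncated to a minimum magnitude of 0.5 (the same threshold defines
  the truth's DE flag). Effects are symmetric in sign, so median-of-ratios
  normalization remains valid; a one-directional effect distribution would
  bias any depth normalization, which is a property of the method family,
  not of this implementation.
- **Zone structure.** Lowland is the reference; a DE gene's highland effect
  is the drawn log2FC, and its midland effect equals the highland effect
  with probability 0.6 (halfway otherwise). This mirrors the observed
  highland-midland similarity and yields DE genes shared between the
  highland and midland comparisons.
- **Nuisance.** Per-gene block effects are N(0, 0.25) in log2 units; size
  factors are log-normal with SD 0.3, renormalized to geometric mean 1;
  dispersion defaults to 0.15, within the usual bulk RNA-seq range. 2% of
  non-candidate genes are withheld from the background list to exercise
  the DE-gene augmentation of the universe.

`paper_like_fixture()` is a preset at 2,000 background genes + 190
candidates with `phi = 4`, dispersion 0.1, strong effects (SD 2, minimum
1) and midland affinity 0.8, sized so that the full pipeline runs in a few
seconds.

What the simulator does *not* emulate: GC or length biases, correlated
gene modules beyond the planted zone structure, outlier libraries, and the
pooling of three plants per library beyond its variance consequences.
Passing tests therefore demonstrate the pipeline's statistical correctness
under a clean negative-binomial world, not robustness to every artifact of
real sequencing data.

## Numerical choices and degenerate inputs

- IRLS: max 50 iterations, relative deviance tolerance 1e-8, linear
  predictor clamped to ±30; non-convergence flags the gene rather than
  aborting the run.
- Dispersion estimates are truncated at 0; a constant gene gets exactly 0.
- Largest-remainder ties break toward the earlier bin, making allocations
  deterministic; the feasibility bound uses a 1e-9 slack against floating
  division.
- Correlation distances clamp tiny negative round-off to 0; zero-variance
  items are an error naming the item.
- Binning uses right-open intervals with a right-closed last bin; a
  degenerate (zero-width) candidate range is an error.
- Empty DE lists yield a summary row with the chi-square marked missing
  rather than a failure.

## Problem sizes used in validation

The test suite validates operating characteristics at sizes chosen to give
stable Monte-Carlo estimates from a handful of seeds: null type-I error on
20 replicates of 300 genes × 45 libraries; power and fold-change recovery
on 200-gene experiments with 60 planted ±2 log2FC genes; enrichment
direction on 20 null and 20 enriched replicates of 3,190 genes;
consensus-clustering recovery on 600–690-gene fixtures at k = 3 with 100
iterations. Oracle-equivalence checks (size factors, BH, correlation
distances, Yates chi-square) run on 100–200 random instances each at
tolerance 1e-10 or tighter.

## Known limitations

- The Wald test with moment-based dispersions is slightly anti-conservative
  in the extreme tail for small per-cell replication; the FDR-level
  operating characteristics are verified by simulation, but single-gene
  p-values near machine precision should not be over-interpreted.
- The list-totals 2×2 construction treats the candidate counts as if
  independent of the totals that contain them; it is reproduced because it
  is the published procedure, and the `nested` alternative is provided for
  conventional analyses.
- Block enters as a fixed effect; split-plot variance components are out of
  scope.
- k = 18 consensus clusters over 45 libraries fragments zones by design
  (the study's setting); zone-level conclusions in the workflow come from
  the consensus tree's top split, not from the 18-cluster partition.
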