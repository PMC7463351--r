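#!/usr/bin/env Rscript
# Depth normalization: median-of-ratios size factors for the 45 libraries,
# compared against the generator's true factors, plus the shifted-log
# variance-stabilized matrix used later for clustering.

library(maizeUVB)

cm <- read_counts("results/sim/counts.tsv",
                  read_metadata("results/sim/metadata.tsv"))
sf <- estimate_size_factors(cm)
dir.create("results/normalization", showWarnings = FALSE, recursive = TRUE)
write_size_factors(sf, "results/normalization/size_factors.tsv")

truth_sf <- read.delim("results/sim/size_factors.tsv")
rel_err <- abs(sf / truth_sf$factor - 1)
cat("size factors in [", round(min(sf), 3), ",", round(max(sf), 3), "]\n")
cat("max relative error vs true factors:", round(max(rel_err), 4), "\n")

norm <- normalize_counts(cm, sf)
vst <- variance_stabilize(norm)
write_counts(round(vst, 4), "results/normalization/vst.tsv")
cat("normalized and variance-stabilized matrix written",
    "(", nrow(vst), "genes x", ncol(vst), "libraries )\n")
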