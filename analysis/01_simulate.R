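#!/usr/bin/env Rscript
# Generate the synthetic common-garden experiment used by the rest of the
# workflow: 45 libraries (3 elevational zones x 5 landraces x 3 blocks),
# 2,000 background genes plus a 190-gene candidate set with a planted
# 4-fold candidate enrichment and strong highland-lowland effects.

library(maizeUVB)

seed <- 20260922 %% 1000L
sim <- paper_like_fixture(seed = seed)
write_simulation(sim, "results/sim")

tr <- sim$truth
cat("libraries:", ncol(sim$counts$counts), "\n")
cat("genes:", nrow(sim$counts$counts),
    "(candidates:", length(sim$candidates$gene_ids), ")\n")
cat("planted DE highland-lowland:", sum(tr$de_highland_lowland),
    "of which candidates:", sum(tr$de_highland_lowland & tr$is_candidate), "\n")
cat("candidate / background planted DE prevalence: ",
    round(mean(tr$de_highland_lowland[tr$is_candidate]) /
            mean(tr$de_highland_lowland[!tr$is_candidate]), 2), "\n")
cat("written to results/sim\n")
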