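#!/usr/bin/env Rscript
# Library-level consensus clustering on the expressed candidate genes
# (1 - Spearman distances, average linkage, 1,000 gene-resampling
# iterations, 18 clusters as in the study settings) and the
# relative-expression heat-map layout for the highland-lowland DE genes
# (1 - Pearson gene clustering, min-max row scaling).

library(maizeUVB)

cm <- read_counts("results/sim/counts.tsv",
                  read_metadata("results/sim/metadata.tsv"))
sf <- estimate_size_factors(cm)
norm <- normalize_counts(cm, sf)
candidates <- read_gene_list("results/sim/candidates.txt", "candidates")
seed <- 20260922 %% 1000L

cand <- intersect(candidates$gene_ids, rownames(norm))
means <- mean_expression(norm, cand)
expressed <- setdiff(cand, attr(means, "zero_genes"))
vst <- variance_stabilize(norm[expressed, , drop = FALSE])
cons <- consensus_cluster(vst, k = 18L, iterations = 1000L, seed = seed)

dir.create("results/clustering", showWarnings = FALSE, recursive = TRUE)
write.table(round(cons$consensus, 4), "results/clustering/consensus_matrix.tsv",
            sep = "\t", quote = FALSE)
write_newick(cons$tree, "results/clustering/consensus_tree.nwk")
write.table(data.frame(sample_id = names(cons$labels), cluster = cons$labels),
            "results/clustering/consensus_labels.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

zone <- cm$samples$zone[match(colnames(cons$consensus), cm$samples$sample_id)]
same <- outer(zone, zone, `==`); diag(same) <- FALSE
cat("mean within-zone consensus:", round(mean(cons$consensus[same]), 3),
    "; between-zone:", round(mean(cons$consensus[!same]), 3), "\n")
two <- cutree(cons$tree, 2)
split_tab <- table(two, zone)
cat("top split vs zone:\n"); print(split_tab)
lowland_isolated <- length(unique(two[zone == "lowland"])) == 1 &&
  !any(two[zone != "lowland"] == two[zone == "lowland"][1])
cat("top split isolates the lowland libraries:",
    if (lowland_isolated) "yes" else "no", "\n")

hl <- read_de_table("results/de/de_highland-lowland.tsv")
de_ids <- hl$gene_id[hl$called]
if (length(de_ids) >= 3) {
  lm_mat <- landrace_means(norm[de_ids, , drop = FALSE], cm$samples)
  heat <- heatmap_order(lm_mat)
  write.table(round(heat$scaled[heat$row_order, ], 4),
              "results/clustering/heatmap_highland-lowland.tsv",
              sep = "\t", quote = FALSE)
  cat("heat-map matrix written for", length(de_ids), "DE genes x",
      ncol(lm_mat), "landraces\n")
}
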