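# Independent brute-force oracles and small fixture builders shared by the
# suite. These deliberately re-derive each quantity from its definition and
# never call the package's own code paths.

# median-of-ratios size factors, literal transcription of the definition
oracle_size_factors <- function(mat) {
  ref_genes <- which(apply(mat, 1L, function(r) all(r > 0)))
  geo <- vapply(ref_genes, function(i) prod(mat[i, ])^(1 / ncol(mat)),
                numeric(1L))
  vapply(seq_len(ncol(mat)), function(j)
    median(mat[ref_genes, j] / geo), numeric(1L))
}

# Benjamini-Hochberg step-up, from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Pearson correlation from first principles
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_corr_dist <- function(mat, method) {
  n <- ncol(mat)
  d <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    xa <- mat[, a]; xb <- mat[, b]
    if (method == "spearman") { xa <- rank(xa); xb <- rank(xb) }
    d[a, b] <- 1 - oracle_pearson(xa, xb)
  }
  diag(d) <- 0
  d
}

# Yates 2x2 chi-square from the textbook formula (correction capped at
# |O - E| so perfect-fit tables score 0)
oracle_yates <- function(obs) {
  e <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum(pmax(0, abs(obs - e) - 0.5)^2 / e)
}

# tiny labelled count matrix for IO tests
tiny_cm <- function(counts = matrix(1:4, 2, 2, byrow = TRUE)) {
  dimnames(counts) <- list(c("g1", "g2"), c("S1", "S2"))
  meta <- data.frame(sample_id = c("S1", "S2"), landrace = c("L1", "L2"),
                     zone = c("lowland", "highland"), block = c("1", "2"),
                     stringsAsFactors = FALSE)
  count_matrix(counts, meta)
}

# 45-sample design metadata (3 zones x 5 landraces x 3 blocks)
design_45 <- function() {
  zones <- rep(c("lowland", "midland", "highland"), each = 5)
  lr <- sprintf("L%02d", 1:15)
  do.call(rbind, lapply(1:15, function(i)
    data.frame(sample_id = sprintf("%s_b%d", lr[i], 1:3),
               landrace = lr[i], zone = zones[i], block = as.character(1:3),
               stringsAsFactors = FALSE)))
}

# direct NB count simulation with explicit per-zone log2 effects; an
# independent construction from the package generator
sim_counts_direct <- function(n_gene, eff_high, eff_mid = 0, mu_range = c(20, 2000),
                              alpha = 0.1, seed = 1) {
  set.seed(seed)
  meta <- design_45()
  mu <- exp(runif(n_gene, log(mu_range[1]), log(mu_range[2])))
  counts <- matrix(0L, n_gene, nrow(meta),
                   dimnames = list(sprintf("g%04d", seq_len(n_gene)),
                                   meta$sample_id))
  eh <- rep_len(eff_high, n_gene)
  em <- rep_len(eff_mid, n_gene)
  for (j in seq_len(nrow(meta))) {
    e <- switch(meta$zone[j], lowland = 0 * eh, midland = em, highland = eh)
    m <- mu * 2^e
    counts[, j] <- if (alpha > 0) rnbinom(n_gene, mu = m, size = 1 / alpha)
                   else rpois(n_gene, m)
  }
  count_matrix(counts, meta)
}

# DE pipeline front half, reused by several tests
de_stage <- function(cm, contrast = zone_contrast("highland", "lowland"),
                     fdr = 0.05) {
  sf <- estimate_size_factors(cm)
  norm <- normalize_counts(cm, sf)
  disp <- estimate_dispersions(norm, cm$samples)
  fit_de(cm, sf, disp, contrast, fdr_threshold = fdr)
}

# one full enrichment pass (highland-lowland) on a simulated experiment,
# built from the exported stage functions
enrichment_once <- function(phi, seed, n_bg = 3000L, de_fraction = 0.2) {
  sim <- simulate_experiment(sim_config(
    n_background_genes = n_bg, n_candidate_genes = 190L,
    de_fraction = de_fraction, phi = phi, lfc_sd = 2, lfc_min = 1,
    dispersion = 0.1, seed = seed))
  sf <- estimate_size_factors(sim$counts)
  norm <- normalize_counts(sim$counts, sf)
  disp <- estimate_dispersions(norm, sim$counts$samples)
  de <- suppressMessages(fit_de(sim$counts, sf, disp,
                                zone_contrast("highland", "lowland")))
  de_set <- suppressMessages(call_de(de))
  cand_means <- mean_expression(norm, intersect(sim$candidates$gene_ids,
                                                rownames(norm)))
  cand_means <- cand_means[cand_means > 0]
  scheme <- filter_bins(compute_bins(cand_means, 10L))
  universe <- suppressMessages(
    build_background(sim$background, de_set, sim$candidates))
  bg_means <- mean_expression(norm, intersect(universe$gene_ids,
                                              rownames(norm)))
  mb <- match_background(bg_means, scheme, seed = seed)
  retained <- names(scheme$assignment)[!is.na(scheme$assignment)]
  cells <- list(candidate_de = length(intersect(de_set$gene_ids, retained)),
                de_total = length(de_set$gene_ids),
                candidate_bg = length(retained), bg_total = mb$total_n)
  rep <- enrichment_report(setNames(list(cells), "highland-lowland"))
  list(report = rep, cells = cells, scheme = scheme, matched = mb)
}
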