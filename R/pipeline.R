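#' Pipeline configuration
#'
#' Collects the analysis settings: input paths (or in-memory objects), the
#' FDR threshold, binning and bin-filter parameters, consensus-clustering
#' settings and seeds.
#'
#' @param counts path to a counts TSV or a [count_matrix()].
#' @param metadata path to a metadata TSV (ignored when `counts` is
#'   already a `count_matrix`).
#' @param candidates path to the candidate gene list or a [gene_set()].
#' @param background path to the background universe list or a
#'   [gene_set()].
#' @param out_dir output directory.
#' @param fdr_threshold DE call cutoff (default 0.05, inclusive).
#' @param n_bins expression bins over the candidate set (default 10).
#' @param bin_min_genes,bin_high_count sparse high-expression bin filter
#'   (drop bins above `bin_high_count` counts with fewer than
#'   `bin_min_genes` candidates).
#' @param consensus_k,consensus_iterations,consensus_frac consensus
#'   clustering settings (study values 18 / 1000 / 0.8).
#' @param seed seed for background matching and consensus resampling.
#' @param nested_table use the conventional nested 2x2 enrichment table
#'   instead of the list-total construction.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, metadata = NULL, candidates, background,
                            out_dir = tempfile("uvbrun"),
                            fdr_threshold = 0.05,
                            n_bins = 10L, bin_min_genes = 3L,
                            bin_high_count = 3000,
                            consensus_k = 18L,
                            consensus_iterations = 1000L,
                            consensus_frac = 0.8,
                            seed = 1L,
                            nested_table = FALSE) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1, n_bins >= 2)
  for (p in list(counts, metadata, candidates, background))
    if (is.character(p) && length(p) == 1L && !file.exists(p))
      stop("input path does not exist: ", p)
  structure(mget(names(formals()), environment()),
            class = "pipeline_config")
}

load_inputs <- function(config) {
  cm <- if (inherits(config$counts, "count_matrix")) config$counts
        else read_counts(config$counts, read_metadata(config$metadata))
  cand <- if (inherits(config$candidates, "gene_set")) config$candidates
          else read_gene_list(config$candidates, "candidates")
  bg <- if (inherits(config$background, "gene_set")) config$background
        else read_gene_list(config$background, "background")
  list(counts = cm, candidates = cand, background = bg)
}

#' Run the full analysis pipeline
#'
#' Normalization, differential expression for the three pairwise zone
#' contrasts, expression-matched candidate enrichment per contrast, and
#' consensus clustering of the libraries on the expressed candidate genes.
#' All stage outputs are written under `config$out_dir` together with a
#' run log recording every parameter and seed used.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `size_factors`, `de` (list of result
#'   tables), `enrichment` (summary data frame), `match` (per-comparison
#'   match diagnostics), `consensus` and `heatmap`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dat <- load_inputs(config)
  cm <- dat$counts
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  sf <- estimate_size_factors(cm)
  write_size_factors(sf, file.path(config$out_dir, "size_factors.tsv"))
  norm <- normalize_counts(cm, sf)
  disp <- estimate_dispersions(norm, cm$samples)

  de_tables <- fit_de_all(cm, sf, disp, fdr_threshold = config$fdr_threshold)
  for (nm in names(de_tables))
    write_de_table(de_tables[[nm]],
                   file.path(config$out_dir, paste0("de_", nm, ".tsv")))

  enr <- enrich_all(norm, de_tables, dat$candidates, dat$background, config)
  utils::write.table(enr$report,
                     file.path(config$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(enr$matched))
    writeLines(enr$matched[[nm]]$gene_ids,
               file.path(config$out_dir, paste0("matched_background_", nm, ".txt")))

  # consensus clustering of libraries on expressed candidate genes
  cand_in <- intersect(dat$candidates$gene_ids, rownames(norm))
  cand_means <- mean_expression(norm, cand_in)
  expressed <- setdiff(cand_in, attr(cand_means, "zero_genes"))
  vst <- variance_stabilize(norm[expressed, , drop = FALSE])
  cons <- consensus_cluster(vst, k = config$consensus_k,
                            iterations = config$consensus_iterations,
                            subsample_frac = config$consensus_frac,
                            seed = config$seed)
  utils::write.table(cons$consensus,
                     file.path(config$out_dir, "consensus_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  write_newick(cons$tree, file.path(config$out_dir, "consensus_tree.nwk"))
  utils::write.table(
    data.frame(sample_id = names(cons$labels), cluster = cons$labels),
    file.path(config$out_dir, "consensus_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # heat-map export for the highland-lowland DE genes
  hl <- de_tables[["highland-lowland"]]
  de_ids <- hl$gene_id[hl$called]
  heat <- NULL
  if (length(de_ids) >= 3L) {
    lm_mat <- landrace_means(norm[de_ids, , drop = FALSE], cm$samples)
    heat <- heatmap_order(lm_mat)
    utils::write.table(
      heat$scaled[heat$row_order, , drop = FALSE],
      file.path(config$out_dir, "heatmap_highland-lowland.tsv"),
      sep = "\t", quote = FALSE)
  }

  write_run_log(config, sf, de_tables, file.path(config$out_dir, "run_log.txt"))
  invisible(list(size_factors = sf, de = de_tables,
                 enrichment = enr$report, match = enr$match,
                 matched = enr$matched, consensus = cons, heatmap = heat))
}

# Enrichment for every contrast: bin the candidates once, then per
# comparison build the augmented background, match it, verify the match,
# and test the 2x2 table.
enrich_all <- function(norm, de_tables, candidates, background, config) {
  cand_in <- intersect(candidates$gene_ids, rownames(norm))
  if (!length(cand_in)) stop("no candidate genes present in the matrix")
  cand_means <- mean_expression(norm, cand_in)
  zero <- attr(cand_means, "zero_genes")
  if (length(zero))
    message(length(zero), " candidate gene(s) with no expression excluded (",
            length(cand_in) - length(zero), " retained)")
  cand_means <- cand_means[setdiff(names(cand_means), zero)]
  scheme <- compute_bins(cand_means, config$n_bins)
  scheme <- filter_bins(scheme, config$bin_min_genes, config$bin_high_count)
  retained_cand <- names(scheme$assignment)[!is.na(scheme$assignment)]

  results <- list(); match <- list(); matched <- list()
  for (nm in names(de_tables)) {
    de_set <- call_de(de_tables[[nm]], config$fdr_threshold)
    universe <- build_background(background, de_set, candidates)
    present <- intersect(universe$gene_ids, rownames(norm))
    bg_means <- mean_expression(norm, present)
    mb <- match_background(bg_means, scheme, seed = config$seed)
    active <- scheme$candidate_counts > 0
    vm <- verify_match(scheme$candidate_counts[active],
                       mb$per_bin_counts[active])
    candidate_de <- length(intersect(de_set$gene_ids, retained_cand))
    results[[nm]] <- list(candidate_de = candidate_de,
                          de_total = length(de_set$gene_ids),
                          candidate_bg = length(retained_cand),
                          bg_total = mb$total_n)
    match[[nm]] <- vm
    matched[[nm]] <- mb
  }
  ok <- vapply(results, function(r) r$de_total > 0, logical(1L))
  report <- enrichment_report(results[ok])
  if (any(!ok)) {
    empty <- data.frame(comparison = names(results)[!ok], chi2 = NA_real_,
                        p = NA_real_, background_ratio = NA_character_,
                        de_ratio = "0/0", enriched = "No",
                        stringsAsFactors = FALSE)
    report <- rbind(report, empty)
    report <- report[match(names(results), report$comparison), ]
  }
  list(report = report, match = match, matched = matched, cells = results)
}

#' Pathway-diagram fill fraction for a fold change
#'
#' Maps a log2 fold change onto the filled-circle scale used in pathway
#' figures: a fully filled circle is `full_scale` (default 2.11, i.e. a
#' 4.32-fold difference); larger changes saturate at 1.
#'
#' @param log2fc finite log2 fold change (first zone over second).
#' @param full_scale log2 fold change shown as a completely filled circle.
#' @return List with `fraction` in `[0, 1]`, `direction` (`up_first_zone`,
#'   `up_second_zone` or `none`) and `legend_fold_change` (`2^full_scale`).
#' @export
fill_fraction <- function(log2fc, full_scale = 2.11) {
  if (!is.finite(log2fc)) stop("log2fc must be finite")
  list(fraction = min(abs(log2fc) / full_scale, 1),
       direction = if (log2fc > 0) "up_first_zone"
                   else if (log2fc < 0) "up_second_zone" else "none",
       legend_fold_change = 2^full_scale)
}

#' Summarize a completed run
#'
#' One row per comparison, column-compatible with the study's enrichment
#' table, plus DE counts.
#'
#' @param run result of [run_pipeline()].
#' @return Data frame: comparison, n_de, n_candidate_de, chi2, p,
#'   background_ratio, de_ratio, enriched.
#' @export
summarize_run <- function(run) {
  rep <- run$enrichment
  n_de <- vapply(strsplit(rep$de_ratio, "/"),
                 function(x) as.integer(x[2L]), integer(1L))
  n_cd <- vapply(strsplit(rep$de_ratio, "/"),
                 function(x) as.integer(x[1L]), integer(1L))
  data.frame(comparison = rep$comparison, n_de = n_de,
             n_candidate_de = n_cd, chi2 = rep$chi2, p = rep$p,
             background_ratio = rep$background_ratio,
             de_ratio = rep$de_ratio, enriched = rep$enriched,
             stringsAsFactors = FALSE)
}

write_run_log <- function(config, sf, de_tables, path) {
  lines <- c(
    paste0("maizeUVB version: ", as.character(utils::packageVersion("maizeUVB"))),
    paste0("fdr_threshold: ", config$fdr_threshold),
    paste0("n_bins: ", config$n_bins),
    paste0("bin_min_genes: ", config$bin_min_genes),
    paste0("bin_high_count: ", config$bin_high_count),
    paste0("consensus_k: ", config$consensus_k),
    paste0("consensus_iterations: ", config$consensus_iterations),
    paste0("consensus_frac: ", config$consensus_frac),
    paste0("seed: ", config$seed),
    paste0("n_samples: ", length(sf)),
    paste0("contrasts: ", paste(names(de_tables), collapse = ", ")))
  writeLines(lines, path)
  invisible(path)
}
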