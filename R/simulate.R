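#' Simulation configuration
#'
#' Parameters of the synthetic experiment: a 3-zone x 5-landrace x 3-block
#' common-garden design (45 pooled libraries), log-normal baseline gene
#' means with candidates drawn from a lower-expression distribution so the
#' expression-matching step is genuinely exercised, negative-binomial
#' counts, per-gene block effects, log-normal library size factors, and
#' planted zone-differential expression whose prevalence among candidates
#' is `phi` times the background prevalence.
#'
#' @param n_background_genes number of non-candidate genes.
#' @param n_candidate_genes number of candidate genes.
#' @param landraces_per_zone landraces per elevational zone.
#' @param blocks number of field blocks.
#' @param mean_log_mu,sd_log_mu log-normal (natural-log) parameters of
#'   background baseline means.
#' @param cand_mean_log_mu,cand_sd_log_mu baseline parameters for
#'   candidate genes (lower mean: most candidates sit in the lowest
#'   expression bin, as in the study).
#' @param dispersion negative-binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`); 0 gives Poisson counts.
#' @param de_fraction probability a background gene is differentially
#'   expressed between highland and lowland.
#' @param lfc_sd standard deviation of planted log2 fold changes.
#' @param lfc_min minimum absolute planted log2 fold change.
#' @param phi candidate enrichment factor (>= 1): candidates are DE with
#'   probability `min(1, phi * de_fraction)`.
#' @param midland_affinity probability a DE gene's midland effect equals
#'   its highland effect (otherwise midland is halfway), mirroring the
#'   highland-midland similarity seen in the study.
#' @param block_sd standard deviation (log2) of per-gene block effects.
#' @param sf_sd standard deviation (natural log) of library size factors.
#' @param absent_frac fraction of non-candidate genes withheld from the
#'   background list (emulating genes absent from the leaf atlas yet DE).
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_background_genes = 12000L,
                       n_candidate_genes = 190L,
                       landraces_per_zone = 5L,
                       blocks = 3L,
                       mean_log_mu = 4, sd_log_mu = 2,
                       cand_mean_log_mu = 2.5, cand_sd_log_mu = 2,
                       dispersion = 0.15,
                       de_fraction = 0.05,
                       lfc_sd = 1.5, lfc_min = 0.5,
                       phi = 1,
                       midland_affinity = 0.6,
                       block_sd = 0.25,
                       sf_sd = 0.3,
                       absent_frac = 0.02,
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_background_genes > 0, n_candidate_genes > 0,
              landraces_per_zone > 0, blocks > 0,
              dispersion >= 0, de_fraction >= 0, de_fraction <= 1,
              lfc_sd > 0, lfc_min >= 0, phi >= 1,
              midland_affinity >= 0, midland_affinity <= 1,
              block_sd >= 0, sf_sd >= 0,
              absent_frac >= 0, absent_frac < 1)
  })
  structure(cfg, class = "sim_config")
}

# truncated normal |x| >= lfc_min via vectorized rejection
rtrunc_lfc <- function(n, sd, min_abs) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, 0, sd)
    out <- c(out, x[abs(x) >= min_abs])
  }
  out[seq_len(n)]
}

#' Simulate a full synthetic experiment
#'
#' Generates counts `K_ij ~ NB(mean = s_j * mu_i * 2^(zone_ij + block_ij),
#' dispersion alpha)` under the configured design, together with sample
#' metadata, candidate and background gene lists, and the ground truth
#' (planted per-contrast log2 fold changes and DE flags, true size
#' factors). Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return List with elements `counts` (a [count_matrix()]), `candidates`
#'   and `background` ([gene_set()]s), and `truth` (data frame, one row per
#'   gene, with attribute `size_factors`).
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng_bg <- config$n_background_genes
  ng_cd <- config$n_candidate_genes
  ngene <- ng_bg + ng_cd
  gene_ids <- c(sprintf("BG%05d", seq_len(ng_bg)),
                sprintf("CAND%04d", seq_len(ng_cd)))
  is_candidate <- c(rep(FALSE, ng_bg), rep(TRUE, ng_cd))

  # design: zones x landraces x blocks, one pooled library per cell
  n_lr <- 3L * config$landraces_per_zone
  zone <- rep(ZONES, each = config$landraces_per_zone)
  landrace <- sprintf("L%02d", seq_len(n_lr))
  samples <- expand.grid(block = as.character(seq_len(config$blocks)),
                         idx = seq_len(n_lr), stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_b%s", landrace[samples$idx], samples$block),
    landrace = landrace[samples$idx],
    zone = zone[samples$idx],
    block = samples$block,
    stringsAsFactors = FALSE)
  nsamp <- nrow(samples)

  # baseline means: candidates from a lower-expression distribution
  mu <- numeric(ngene)
  mu[!is_candidate] <- stats::rlnorm(ng_bg, config$mean_log_mu, config$sd_log_mu)
  mu[is_candidate] <- stats::rlnorm(ng_cd, config$cand_mean_log_mu,
                                    config$cand_sd_log_mu)

  # planted DE: candidates phi-fold more likely to be DE
  p_de <- ifelse(is_candidate,
                 pmin(1, config$phi * config$de_fraction),
                 config$de_fraction)
  is_de <- stats::runif(ngene) < p_de
  eff_high <- numeric(ngene)
  eff_mid <- numeric(ngene)
  nde <- sum(is_de)
  if (nde > 0) {
    e <- rtrunc_lfc(nde, config$lfc_sd, config$lfc_min)
    share <- stats::runif(nde) < config$midland_affinity
    eff_high[is_de] <- e
    eff_mid[is_de] <- ifelse(share, e, e / 2)
  }

  # per-gene block effects (log2), block 1 as reference
  block_eff <- matrix(0, ngene, config$blocks)
  if (config$block_sd > 0 && config$blocks > 1)
    block_eff[, -1L] <- stats::rnorm(ngene * (config$blocks - 1L),
                                     0, config$block_sd)

  # library size factors, geometric mean 1
  sf <- exp(stats::rnorm(nsamp, 0, config$sf_sd))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- samples$sample_id

  zone_eff <- rbind(lowland = 0, midland = eff_mid, highland = eff_high)
  counts <- matrix(0L, ngene, nsamp,
                   dimnames = list(gene_ids, samples$sample_id))
  for (j in seq_len(nsamp)) {
    z <- samples$zone[j]
    b <- as.integer(samples$block[j])
    log2x <- zone_eff[z, ] + block_eff[, b]
    m <- sf[j] * mu * 2^log2x
    counts[, j] <- if (config$dispersion > 0)
      stats::rnbinom(ngene, mu = m, size = 1 / config$dispersion)
    else stats::rpois(ngene, m)
  }

  lfc_hl <- eff_high
  lfc_hm <- eff_high - eff_mid
  lfc_ml <- eff_mid
  thr <- config$lfc_min
  truth <- data.frame(
    gene_id = gene_ids, is_candidate = is_candidate, mu = mu,
    lfc_highland_lowland = lfc_hl, de_highland_lowland = abs(lfc_hl) >= thr,
    lfc_highland_midland = lfc_hm, de_highland_midland = abs(lfc_hm) >= thr,
    lfc_midland_lowland = lfc_ml, de_midland_lowland = abs(lfc_ml) >= thr,
    stringsAsFactors = FALSE)
  attr(truth, "size_factors") <- sf

  bg_ids <- gene_ids[!is_candidate]
  if (config$absent_frac > 0) {
    drop <- sample.int(length(bg_ids), round(config$absent_frac * length(bg_ids)))
    if (length(drop)) bg_ids <- bg_ids[-drop]
  }
  list(counts = count_matrix(counts, samples),
       candidates = gene_set("candidates", gene_ids[is_candidate]),
       background = gene_set("background", bg_ids),
       truth = truth)
}

#' Small preset emulating the study
#'
#' 2,000 background genes plus the 190-gene candidate set, candidate
#' enrichment factor 4, strong highland-lowland effects with midland
#' usually siding with highland -- sized so the full pipeline runs in
#' well under two minutes.
#'
#' @param seed integer seed.
#' @return As [simulate_experiment()].
#' @export
paper_like_fixture <- function(seed = 1L) {
  simulate_experiment(sim_config(
    n_background_genes = 2000L, n_candidate_genes = 190L,
    dispersion = 0.1, de_fraction = 0.05, phi = 4,
    lfc_sd = 2, lfc_min = 1, midland_affinity = 0.8,
    seed = seed))
}

#' Write a simulated experiment to a directory
#'
#' Emits counts.tsv, metadata.tsv, candidates.txt, background.txt,
#' truth.tsv and size_factors.tsv in the package's file formats.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_metadata(sim$counts$samples, file.path(dir, "metadata.tsv"))
  write_gene_list(sim$candidates, file.path(dir, "candidates.txt"))
  write_gene_list(sim$background, file.path(dir, "background.txt"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_size_factors(attr(sim$truth, "size_factors"),
                     file.path(dir, "size_factors.tsv"))
  invisible(dir)
}
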