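#' Mean normalized expression of a gene set
#'
#' Arithmetic mean of normalized counts across all samples for each gene in
#' the set. Genes absent from the matrix are an error; genes with zero
#' expression in every sample are reported so callers can drop them before
#' binning.
#'
#' @param norm normalized count matrix (genes x samples).
#' @param genes a [gene_set()] or character vector of gene IDs.
#' @return Named numeric vector of per-gene means, with an attribute
#'   `zero_genes` listing all-zero members.
#' @export
mean_expression <- function(norm, genes) {
  ids <- if (inherits(genes, "gene_set")) genes$gene_ids else as.character(genes)
  missing <- setdiff(ids, rownames(norm))
  if (length(missing))
    stop("genes absent from the matrix: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  m <- rowMeans(norm[ids, , drop = FALSE])
  attr(m, "zero_genes") <- ids[m == 0]
  m
}

#' Equal-width expression bins over the candidate set
#'
#' Divides the candidate genes into `n_bins` bins of equal width spanning
#' the range of their average normalized expression. Intervals are
#' right-open except the last, which is right-closed, so every gene falls
#' in exactly one bin.
#'
#' @param candidate_means named vector of candidate mean expression (zero
#'   genes already removed).
#' @param n_bins number of bins; default 10.
#' @return A `bin_scheme`: list with `n_bins`, `edges` (length
#'   `n_bins + 1`), `candidate_counts`, `candidate_props` and `assignment`
#'   (per-gene bin index, named).
#' @export
compute_bins <- function(candidate_means, n_bins = 10L) {
  x <- candidate_means
  if (length(unique(x)) < n_bins)
    stop("need at least ", n_bins, " distinct expression values")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("degenerate expression range: max equals min")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  assignment <- bin_assign(x, edges)
  counts <- tabulate(assignment, nbins = n_bins)
  structure(list(n_bins = n_bins, edges = edges,
                 candidate_counts = counts,
                 candidate_props = counts / sum(counts),
                 assignment = assignment),
            class = "bin_scheme")
}

# Right-open intervals, last bin right-closed; values outside [min, max]
# get NA.
bin_assign <- function(x, edges) {
  n_bins <- length(edges) - 1L
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[x < edges[1L] | x > edges[n_bins + 1L]] <- NA_integer_
  idx[idx == 0L] <- NA_integer_
  names(idx) <- names(x)
  idx
}

#' Drop sparse high-expression bins
#'
#' Bins lying above the high-count threshold that contain fewer than
#' `min_genes` candidate genes are removed and their genes dropped from the
#' candidate working set; the remaining per-bin proportions are
#' renormalized. With the study's occupancy (156 and 15 genes in the first
#' two bins, a sparse tail) this reduces 179 candidates to 175.
#'
#' @param scheme a `bin_scheme` from [compute_bins()].
#' @param min_genes bins with fewer candidates than this are removable;
#'   default 3 (i.e. two or fewer genes).
#' @param high_count_threshold only bins whose lower edge exceeds this
#'   normalized-count level are removable; default 3000.
#' @return A filtered `bin_scheme` with an added `retained` logical vector
#'   over bins and `dropped_genes` listing removed candidates.
#' @export
filter_bins <- function(scheme, min_genes = 3L, high_count_threshold = 3000) {
  lower <- scheme$edges[seq_len(scheme$n_bins)]
  drop <- lower > high_count_threshold & scheme$candidate_counts < min_genes
  if (all(drop)) stop("bin filter removed every bin")
  assignment <- scheme$assignment
  dropped_genes <- names(assignment)[!is.na(assignment) & drop[assignment]]
  assignment[!is.na(assignment) & drop[assignment]] <- NA_integer_
  counts <- scheme$candidate_counts
  counts[drop] <- 0L
  out <- scheme
  out$candidate_counts <- counts
  out$candidate_props <- counts / sum(counts)
  out$assignment <- assignment
  out$retained <- !drop
  out$dropped_genes <- dropped_genes
  out
}

#' Assemble the background universe for one comparison
#'
#' Union of the expressed-gene universe, the DE genes for the comparison
#' (which may include genes missing from the leaf universe) and the
#' candidate genes themselves.
#'
#' @param universe,de_genes,candidates [gene_set()]s or character vectors.
#' @return A [gene_set()] named after the union.
#' @export
build_background <- function(universe, de_genes, candidates) {
  ids <- function(x) if (inherits(x, "gene_set")) x$gene_ids else as.character(x)
  u <- union(union(ids(universe), ids(de_genes)), ids(candidates))
  message("background universe: ", length(u), " genes")
  gene_set("background", u)
}

# Largest-remainder apportionment of N across bins by target proportions.
# Deterministic tie-break: earlier bin wins.
quota_allocate <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, -seq_along(props), decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Expression-matched background subsample
#'
#' Draws the largest background subsample whose per-bin composition matches
#' the candidate proportions: N is the largest total for which the
#' largest-remainder quotas fit within per-bin availability, and quota
#' genes are then drawn uniformly without replacement within each bin.
#' Background genes with mean expression outside the candidate bin range
#' are excluded before matching.
#'
#' @param background_means named vector of background mean expression.
#' @param scheme (filtered) `bin_scheme` of the candidate set.
#' @param seed integer seed controlling the within-bin draws.
#' @return A `matched_background`: list with `gene_ids`, `per_bin_counts`,
#'   `total_n`, `n_out_of_range`, `availability` and `seed`.
#' @export
match_background <- function(background_means, scheme, seed = 1L) {
  assignment <- bin_assign(background_means, scheme$edges)
  if (!is.null(scheme$retained))
    assignment[!is.na(assignment) & !scheme$retained[assignment]] <- NA_integer_
  n_out <- sum(is.na(assignment))
  avail <- tabulate(assignment, nbins = scheme$n_bins)
  props <- scheme$candidate_props
  active <- props > 0
  empty <- which(active & avail == 0L)
  if (length(empty))
    stop("no background genes available in retained bin(s) ",
         paste(empty, collapse = ", "))
  # largest N with ceiling(N * p_k) <= avail_k in every active bin; this
  # guarantees the largest-remainder quotas (each <= ceiling(N * p_k)) fit
  n <- as.integer(min(floor(avail[active] / props[active] + 1e-9)))
  if (n <= 0L) stop("matching failed: no feasible subsample size")
  quotas <- quota_allocate(n, props)
  stopifnot(all(quotas <= avail))
  by_bin <- split(names(assignment)[!is.na(assignment)],
                  assignment[!is.na(assignment)])
  chosen <- character(0)
  rng <- local({
    set.seed(seed)
    lapply(seq_len(scheme$n_bins), function(k) {
      if (quotas[k] == 0L) return(character(0))
      pool <- by_bin[[as.character(k)]]
      pool[sample.int(length(pool), quotas[k])]
    })
  })
  chosen <- unlist(rng, use.names = FALSE)
  structure(list(gene_ids = chosen, per_bin_counts = quotas, total_n = n,
                 n_out_of_range = n_out, availability = avail, seed = seed),
            class = "matched_background")
}

#' Verify the candidate / matched-background distribution match
#'
#' Two-sample chi-square on the bins-by-list contingency table of candidate
#' versus matched counts. Bins empty in both lists are dropped with a
#' warning; the Yates continuity correction is applied only when exactly
#' two bins remain. A match is declared when p > 0.95.
#'
#' @param candidate_counts,matched_counts per-bin gene counts on the same
#'   bins.
#' @return List with `chi2`, `p` and `matched` (logical).
#' @export
verify_match <- function(candidate_counts, matched_counts) {
  if (length(candidate_counts) != length(matched_counts))
    stop("bin count vectors differ in length")
  if (sum(candidate_counts) == 0 || sum(matched_counts) == 0)
    stop("both lists must be non-empty")
  keep <- (candidate_counts + matched_counts) > 0
  if (any(!keep)) {
    warning(sum(!keep), " empty bin(s) dropped from the match test")
    candidate_counts <- candidate_counts[keep]
    matched_counts <- matched_counts[keep]
  }
  tab <- cbind(candidate = candidate_counts, matched = matched_counts)
  res <- suppressWarnings(
    stats::chisq.test(tab, correct = nrow(tab) == 2L))
  list(chi2 = unname(res$statistic), p = unname(res$p.value),
       matched = res$p.value > 0.95)
}

#' Yates-corrected chi-square on a 2x2 enrichment table
#'
#' The four inputs are used directly as the four cells of the table
#' `[[candidate_de, de_total], [candidate_bg, bg_total]]` -- the list-total
#' construction in which each row holds a list's candidate count next to
#' its overall size. Expected cells come from the row/column margins; each
#' cell contributes `(max(0, |O - E| - 0.5))^2 / E`, so a perfect-fit table
#' scores exactly 0; p is the upper tail of chi-square with 1 df.
#'
#' With `nested = TRUE` the conventional candidate-in/out by DE-in/out
#' partition is used instead: cells `[[candidate_de, candidate_bg -
#' candidate_de], [de_total - candidate_de, bg_total - candidate_bg -
#' de_total + candidate_de]]`.
#'
#' @param candidate_de candidate genes in the DE list.
#' @param de_total size of the DE list.
#' @param candidate_bg candidate genes in the background list.
#' @param bg_total size of the background list.
#' @param nested use the conventional nested 2x2 partition.
#' @return List with `chi2`, `p` and the `table` used.
#' @export
yates_chi2 <- function(candidate_de, de_total, candidate_bg, bg_total,
                       nested = FALSE) {
  cells <- c(candidate_de, de_total, candidate_bg, bg_total)
  if (any(cells < 0)) stop("counts must be non-negative")
  if (nested) {
    obs <- matrix(c(candidate_de, candidate_bg - candidate_de,
                    de_total - candidate_de,
                    bg_total - candidate_bg - de_total + candidate_de),
                  2L, 2L, byrow = TRUE)
    if (any(obs < 0)) stop("nested table has negative cells; check inputs")
  } else {
    obs <- matrix(c(candidate_de, de_total, candidate_bg, bg_total),
                  2L, 2L, byrow = TRUE)
  }
  if (sum(obs) == 0) stop("table total is zero")
  rs <- rowSums(obs); cs <- colSums(obs)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in 2x2 table")
  expected <- outer(rs, cs) / sum(obs)
  dev <- pmax(0, abs(obs - expected) - 0.5)
  chi2 <- sum(dev^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       table = obs)
}

#' Enrichment summary across contrasts
#'
#' One row per zone comparison with the 2x2 cells, the Yates chi-square,
#' its p-value and the enrichment call. A comparison is enriched only when
#' p < 0.05 *and* the candidate rate in the DE list exceeds the candidate
#' rate in the matched background (significant depletion is not
#' enrichment).
#'
#' @param results named list (one element per comparison), each with
#'   fields `candidate_de`, `de_total`, `candidate_bg`, `bg_total`.
#' @param alpha significance level; default 0.05.
#' @return Data frame shaped like the study's enrichment table: comparison,
#'   chi2, p, background_ratio, de_ratio, enriched.
#' @export
enrichment_report <- function(results, alpha = 0.05) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    test <- yates_chi2(r$candidate_de, r$de_total, r$candidate_bg, r$bg_total)
    up <- (r$candidate_de / r$de_total) > (r$candidate_bg / r$bg_total)
    data.frame(comparison = nm,
               chi2 = test$chi2, p = test$p,
               background_ratio = paste0(r$candidate_bg, "/", r$bg_total),
               de_ratio = paste0(r$candidate_de, "/", r$de_total),
               enriched = ifelse(test$p < alpha & up, "Yes", "No"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
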