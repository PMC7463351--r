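#' Correlation distance between matrix columns
#'
#' `1 - cor` between items (columns), with Spearman (average ranks for
#' ties) or Pearson correlation; distances lie in `[0, 2]`.
#'
#' @param mat numeric matrix, features in rows, items in columns.
#' @param method `"spearman"` or `"pearson"`.
#' @return Symmetric distance matrix with zero diagonal and the column
#'   names of `mat` as labels.
#' @export
correlation_distance <- function(mat, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (nrow(mat) < 3L) stop("need at least 3 features per item")
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance item(s): ",
         paste(colnames(mat)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(mat, method = method)
  d[d < 0] <- 0  # guard tiny negative round-off
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering
#'
#' UPGMA agglomeration on a precomputed distance matrix, cut into `k`
#' groups.
#'
#' @param d symmetric distance matrix.
#' @param k number of clusters (capped at the number of items).
#' @return List with `labels` (named cluster assignment) and `tree`
#'   (an `hclust` object).
#' @export
hclust_average <- function(d, k) {
  if (k < 1L) stop("k must be at least 1")
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  k <- min(k, nrow(as.matrix(d)))
  labels <- stats::cutree(tree, k = k)
  list(labels = labels, tree = tree)
}

#' Resampling consensus clustering of libraries
#'
#' For each iteration a random `subsample_frac` fraction of the features
#' (genes) is drawn without replacement, items (libraries) are clustered at
#' `k` with average linkage on one-minus-Spearman distances, and
#' co-membership is recorded. The consensus matrix is the fraction of
#' iterations in which two libraries landed in the same cluster (all
#' libraries are present in every iteration, so the denominator is
#' `iterations`). A final average-linkage tree on one minus the consensus
#' gives the reported partition.
#'
#' @param mat numeric matrix, genes in rows, libraries in columns
#'   (variance-stabilized normalized counts).
#' @param k number of clusters; study setting 18.
#' @param iterations number of resampling iterations; study setting 1000.
#' @param subsample_frac fraction of genes drawn per iteration.
#' @param seed integer seed; the run is fully reproducible from it.
#' @param method correlation used within iterations.
#' @return A `consensus_result`: list with `consensus` (matrix in
#'   `[0, 1]`, unit diagonal), `tree` (`hclust` on 1 - consensus),
#'   `labels` (partition at `k`) and the settings used.
#' @export
consensus_cluster <- function(mat, k = 18L, iterations = 1000L,
                              subsample_frac = 0.8, seed = 1L,
                              method = "spearman") {
  if (iterations < 1L) stop("iterations must be at least 1")
  if (subsample_frac <= 0 || subsample_frac > 1)
    stop("subsample_frac must be in (0, 1]")
  n_items <- ncol(mat)
  n_feat <- nrow(mat)
  n_draw <- ceiling(subsample_frac * n_feat)
  co <- matrix(0, n_items, n_items,
               dimnames = list(colnames(mat), colnames(mat)))
  set.seed(seed)
  for (it in seq_len(iterations)) {
    feats <- sample.int(n_feat, n_draw)
    d <- correlation_distance(mat[feats, , drop = FALSE], method)
    lab <- hclust_average(d, k)$labels
    co <- co + outer(lab, lab, `==`)
  }
  consensus <- co / iterations
  diag(consensus) <- 1
  final <- hclust_average(1 - consensus, k)
  structure(list(consensus = consensus, tree = final$tree,
                 labels = final$labels, k = k, iterations = iterations,
                 subsample_frac = subsample_frac, seed = seed),
            class = "consensus_result")
}

#' Heat-map ordering and row scaling for DE genes
#'
#' Scales each gene (row) to `[0, 1]` (minimum to 0, maximum to 1;
#' constant rows become 0.5 with a warning) and orders rows by an
#' average-linkage dendrogram on one-minus-Pearson distances between gene
#' profiles, the layout used for relative-expression heat maps.
#'
#' @param de_matrix normalized counts for the DE genes, typically
#'   aggregated to landrace means (genes x landraces).
#' @return List with `scaled` (row-scaled matrix), `row_order`,
#'   `col_order` and `gene_tree`.
#' @export
heatmap_order <- function(de_matrix) {
  rng <- apply(de_matrix, 1L, function(r) diff(range(r)))
  scaled <- de_matrix
  if (any(rng == 0)) {
    warning(sum(rng == 0), " constant row(s) scaled to 0.5")
    scaled[rng == 0, ] <- 0.5
  }
  ok <- rng > 0
  scaled[ok, ] <- (de_matrix[ok, , drop = FALSE] -
                     apply(de_matrix[ok, , drop = FALSE], 1L, min)) / rng[ok]
  if (sum(ok) >= 3L && ncol(de_matrix) >= 3L) {
    d <- correlation_distance(t(de_matrix[ok, , drop = FALSE]), "pearson")
    tree <- stats::hclust(stats::as.dist(d), method = "average")
    row_order <- c(which(ok)[tree$order], which(!ok))
  } else {
    tree <- NULL
    row_order <- seq_len(nrow(de_matrix))
  }
  list(scaled = scaled, row_order = row_order,
       col_order = seq_len(ncol(de_matrix)), gene_tree = tree)
}

#' Aggregate normalized counts to landrace means
#'
#' @param norm normalized matrix (genes x samples).
#' @param samples metadata aligned to columns.
#' @return Matrix of per-landrace mean expression, landraces ordered by
#'   zone (lowland, midland, highland) then ID.
#' @export
landrace_means <- function(norm, samples) {
  samples <- validate_samples(samples)
  key <- samples$landrace
  zone_of <- tapply(samples$zone, key, `[`, 1L)
  groups <- split(seq_len(ncol(norm)), key)
  m <- vapply(groups, function(j) rowMeans(norm[, j, drop = FALSE]),
              numeric(nrow(norm)))
  ord <- order(match(zone_of[colnames(m)], ZONES), colnames(m))
  m[, ord, drop = FALSE]
}

#' Export a dendrogram as Newick
#'
#' @param tree an `hclust` object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
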