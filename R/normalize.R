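#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth scale factors: each sample's factor is the
#' median, over genes expressed in every sample, of the ratio of that
#' sample's count to the gene's geometric mean across samples. Genes with a
#' zero in any sample are excluded from the reference; the geometric mean is
#' computed in log space to avoid overflow.
#'
#' @param counts a [count_matrix()] or integer matrix (genes x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  mat <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  keep <- rowSums(mat == 0) == 0L
  if (!any(keep))
    stop("no gene has strictly positive counts in all samples; ",
         "pre-filter low-coverage genes or samples before normalization")
  logm <- log(mat[keep, , drop = FALSE])
  logref <- rowMeans(logm)  # log geometric mean per gene
  sf <- apply(logm, 2L, function(col) stats::median(exp(col - logref)))
  names(sf) <- colnames(mat)
  sf
}

#' Normalize counts by size factors
#'
#' Divides each sample's counts by its size factor, giving real-valued
#' depth-equalized expression values.
#'
#' @param counts a [count_matrix()] or matrix.
#' @param sf size factors aligned to the samples (from
#'   [estimate_size_factors()]).
#' @return Numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf) {
  mat <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (length(sf) != ncol(mat))
    stop("length(sf) = ", length(sf), " but matrix has ", ncol(mat), " samples")
  if (any(sf <= 0)) stop("size factors must be positive")
  if (!is.null(names(sf)) && !is.null(colnames(mat)) &&
      !identical(names(sf), colnames(mat)))
    stop("size factor names do not match sample order")
  sweep(mat, 2L, sf, `/`)
}

#' Shifted-log variance stabilization
#'
#' log2(x + 1) on normalized counts: monotone, maps zero to zero, and damps
#' the mean-variance coupling of count data ahead of correlation-based
#' clustering, which depends only on rank and linear structure.
#'
#' @param x non-negative numeric matrix or vector of normalized counts.
#' @return Transformed values, same shape as `x`.
#' @export
variance_stabilize <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("negative entries cannot be stabilized")
  log2(x + 1)
}

#' @rdname estimate_size_factors
#' @param sf named size-factor vector.
#' @param path output TSV path (columns sample_id, factor).
#' @export
write_size_factors <- function(sf, path) {
  utils::write.table(
    data.frame(sample_id = names(sf), factor = unname(sf)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
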