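#' @keywords internal
"_PACKAGE"

ZONES <- c("lowland", "midland", "highland")
BLOCKS <- c("1", "2", "3")

#' Construct a count matrix object
#'
#' Bundles an integer gene-by-sample count matrix with per-sample factors
#' (landrace, elevational zone of origin, field block), the unit every
#' downstream stage consumes.
#'
#' @param counts integer matrix, genes in rows, samples in columns, with
#'   row and column names.
#' @param samples data frame with columns `sample_id`, `landrace`, `zone`
#'   (one of lowland/midland/highland) and `block` (1-3), one row per
#'   column of `counts`, in the same order.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  samples <- validate_samples(samples)
  if (nrow(samples) != ncol(counts))
    stop("metadata has ", nrow(samples), " rows but counts has ",
         ncol(counts), " columns")
  if (!identical(samples$sample_id, colnames(counts)))
    stop("sample order in metadata must match the count matrix header; ",
         "mismatch is an error, not a silent reorder")
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

validate_samples <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "landrace", "zone", "block")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  samples$landrace <- as.character(samples$landrace)
  zone <- tolower(trimws(as.character(samples$zone)))
  bad <- setdiff(unique(zone), ZONES)
  if (length(bad))
    stop("unknown zone label(s): ", paste(bad, collapse = ", "),
         " (expected lowland/midland/highland)")
  samples$zone <- zone
  block <- as.character(samples$block)
  bad <- setdiff(unique(block), BLOCKS)
  if (length(bad))
    stop("unknown block label(s): ", paste(bad, collapse = ", "),
         " (expected 1, 2 or 3)")
  samples$block <- block
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample IDs in metadata")
  rownames(samples) <- NULL
  samples[, need]
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("zones:", paste(sprintf("%s=%d", names(table(x$samples$zone)),
                              table(x$samples$zone)), collapse = " "), "\n")
  invisible(x)
}

#' Subset a count matrix by sample
#'
#' Keeps counts and sample metadata aligned; `j` indexes columns.
#'
#' @param x a [count_matrix()].
#' @param j column (sample) index, logical, integer or character.
#' @return A `count_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(x, j) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts[, j, drop = FALSE]
  idx <- match(colnames(counts), x$samples$sample_id)
  count_matrix(counts, x$samples[idx, , drop = FALSE])
}

#' Read a gene-level count matrix
#'
#' Expects a tab-separated file with a header row of sample IDs and gene IDs
#' in the first column. Cells must be non-negative integers; ragged rows,
#' negative or non-integer cells, and duplicate IDs are errors. Genes with
#' all-zero counts are retained -- filtering them is an explicit downstream
#' step.
#'
#' @param path path to the TSV file.
#' @param samples optional sample metadata data frame (as from
#'   [read_metadata()]); if supplied, attached and checked for alignment.
#' @return A `count_matrix` if `samples` is given, otherwise the bare
#'   integer matrix.
#' @export
read_counts <- function(path, samples = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("count file has no data rows: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  ncell <- length(sample_ids)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield != ncell + 1L))
    stop("ragged row ", which(nfield != ncell + 1L)[1L] + 1L, " in ", path,
         ": expected ", ncell + 1L, " fields")
  gene_ids <- vapply(rows, `[[`, character(1L), 1L)
  cells <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1L]), numeric(ncell)))
  mat <- matrix(if (ncell == 1L) cells else t(cells),
                nrow = length(gene_ids), ncol = ncell, byrow = FALSE,
                dimnames = list(gene_ids, sample_ids))
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count for gene '",
         gene_ids[bad[1L, 1L]], "', sample '", sample_ids[bad[1L, 2L]],
         "' in ", path)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene IDs in ", path, ": ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 5L),
               collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs in ", path)
  storage.mode(mat) <- "integer"
  if (is.null(samples)) mat else count_matrix(mat, samples)
}

#' Write a count matrix to TSV
#'
#' @param x a `count_matrix` or a matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  mat <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, paste, collapse = "\t")
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated table with columns `sample_id`, `landrace`, `zone`, `block`.
#' Zone labels are case-normalized; unknown zones or blocks are errors. Row
#' order is preserved.
#'
#' @param path path to the TSV file.
#' @return Data frame of per-sample factors.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          fileEncoding = "UTF-8", check.names = FALSE)
  validate_samples(df)
}

#' @rdname read_metadata
#' @param samples metadata data frame to write.
#' @export
write_metadata <- function(samples, path) {
  utils::write.table(validate_samples(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene list
#'
#' One gene ID per line; blank lines and lines starting with `#` are ignored;
#' duplicates are collapsed with a warning. An empty result is an error.
#'
#' @param path path to the list file.
#' @param name label for the set (defaults to the file name).
#' @return A `gene_set`: list with `name` and a character vector `gene_ids`.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (anyDuplicated(lines)) {
    ndup <- sum(duplicated(lines))
    warning(ndup, " duplicate gene ID(s) collapsed in ", path)
    lines <- unique(lines)
  }
  if (!length(lines)) stop("gene list is empty: ", path)
  message("read ", length(lines), " unique gene IDs from ", path)
  gene_set(name, lines)
}

#' @rdname read_gene_list
#' @param gene_ids character vector of gene identifiers (non-empty, unique).
#' @export
gene_set <- function(name, gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (!length(gene_ids)) stop("gene set '", name, "' is empty")
  if (anyDuplicated(gene_ids)) stop("gene set '", name, "' has duplicates")
  structure(list(name = name, gene_ids = gene_ids), class = "gene_set")
}

#' @rdname read_gene_list
#' @param set a `gene_set` to write.
#' @export
write_gene_list <- function(set, path) {
  writeLines(set$gene_ids, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$gene_ids), " genes\n", sep = "")
  invisible(x)
}

#' Write a differential-expression result table
#'
#' TSV with a comment header line naming the contrast, then columns
#' gene_id, base_mean, log2fc, se, wald, p, fdr, called.
#'
#' @param tab result data frame from [fit_de()].
#' @param path output path.
#' @export
write_de_table <- function(tab, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# contrast: ", attr(tab, "contrast")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (startsWith(first, "# contrast: "))
    attr(tab, "contrast") <- sub("^# contrast: ", "", first)
  tab
}
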