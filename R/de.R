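#' The three pairwise zone contrasts
#'
#' A contrast compares expression between two elevational zones; the log2
#' fold change is reported as the first zone over the second, so a positive
#' value means higher expression in the first-named zone.
#'
#' @param zone_a,zone_b distinct zones from lowland/midland/highland.
#' @return A `zone_contrast` object.
#' @export
zone_contrast <- function(zone_a, zone_b) {
  zone_a <- match.arg(zone_a, ZONES)
  zone_b <- match.arg(zone_b, ZONES)
  if (zone_a == zone_b) stop("contrast zones must differ")
  structure(list(zone_a = zone_a, zone_b = zone_b),
            class = "zone_contrast")
}

#' @rdname zone_contrast
#' @export
all_contrasts <- function() {
  list(zone_contrast("highland", "lowland"),
       zone_contrast("highland", "midland"),
       zone_contrast("midland", "lowland"))
}

contrast_label <- function(ct) paste0(ct$zone_a, "-", ct$zone_b)

#' Gene-wise negative-binomial dispersion estimates
#'
#' Method-of-moments dispersion per gene from normalized counts pooled
#' within zone-by-block cells (so zone and block differences do not inflate
#' the estimate): alpha = max(0, (var - mean) / mean^2) per cell, pooled
#' with degrees-of-freedom weights, then shrunk halfway toward a
#' mean--dispersion trend obtained by lowess smoothing of the raw
#' estimates against log mean expression.
#'
#' @param norm normalized count matrix (genes x samples).
#' @param samples sample metadata data frame aligned to the columns.
#' @return A list with `alpha` (shrunken per-gene dispersion), `raw`
#'   (method-of-moments estimate), `trend` (fitted trend value) and
#'   `mean` (per-gene mean normalized count).
#' @export
estimate_dispersions <- function(norm, samples) {
  samples <- validate_samples(samples)
  if (ncol(norm) != nrow(samples))
    stop("metadata does not match matrix columns")
  cell <- interaction(samples$zone, samples$block, drop = TRUE)
  if (min(table(cell)) < 2L)
    stop("each zone x block cell needs at least 2 samples to estimate ",
         "dispersion; smallest cell has ", min(table(cell)))
  idx <- split(seq_len(ncol(norm)), cell)
  raw <- rep(0, nrow(norm))
  for (cols in idx) {
    m <- rowMeans(norm[, cols, drop = FALSE])
    v <- apply(norm[, cols, drop = FALSE], 1L, stats::var)
    a <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    w <- length(cols) - 1L
    raw <- raw + ifelse(is.na(a), 0, a * w)
  }
  df <- sum(vapply(idx, length, integer(1L)) - 1L)
  raw <- pmax(0, raw / df)
  mu <- rowMeans(norm)
  # trend over expressed genes; flat extrapolation outside the fitted range
  ok <- mu > 0
  trend <- rep(0, length(mu))
  if (sum(ok) >= 10L) {
    lx <- log10(mu[ok] + 1)
    sm <- stats::lowess(lx, raw[ok], f = 0.5)
    trend[ok] <- pmax(0, stats::approx(sm$x, sm$y, xout = lx, rule = 2L,
                                       ties = mean)$y)
  }
  alpha <- 0.5 * raw + 0.5 * trend
  names(alpha) <- names(raw) <- names(trend) <- names(mu) <- rownames(norm)
  list(alpha = alpha, raw = raw, trend = trend, mean = mu)
}

# NB deviance with fixed dispersion; alpha = 0 reduces to Poisson.
nb_deviance <- function(y, mu, alpha) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (alpha <= 0) {
    2 * sum(t1 - (y - mu))
  } else {
    2 * sum(t1 - (y + 1 / alpha) * log((1 + alpha * y) / (1 + alpha * mu)))
  }
}

# IRLS fit of a log-link NB GLM with fixed dispersion and offset.
# Returns coefficients, their covariance (expected information), and a
# convergence flag. max 50 iterations, relative deviance tolerance 1e-8.
nb_irls <- function(y, X, offset, alpha, max_iter = 50L, tol = 1e-8) {
  if (all(y == 0))
    return(list(beta = rep(NA_real_, ncol(X)), cov = NULL, converged = FALSE))
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  dev <- nb_deviance(y, mu, alpha)
  beta <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients))
      return(list(beta = rep(NA_real_, ncol(X)), cov = NULL, converged = FALSE))
    beta <- fit$coefficients
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    dev_new <- nb_deviance(y, mu, alpha)
    if (!is.finite(dev_new)) break
    if (abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol) {
      converged <- TRUE
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X, X * w)
  cov <- tryCatch(solve(xtwx), error = function(e) NULL)
  if (is.null(cov)) converged <- FALSE
  list(beta = beta, cov = cov, converged = converged)
}

# Fit the two-factor NB model once per gene; shared by all contrasts.
nb_fit_all <- function(cm, sf, disp) {
  stopifnot(inherits(cm, "count_matrix"))
  samples <- cm$samples
  zone <- factor(samples$zone, levels = ZONES)
  block <- factor(samples$block, levels = BLOCKS)
  if (any(table(zone, block) == 0))
    stop("design must observe every zone in every block")
  X <- stats::model.matrix(~ block + zone)
  offset <- log(sf)
  ngene <- nrow(cm$counts)
  beta <- matrix(NA_real_, ngene, ncol(X),
                 dimnames = list(rownames(cm$counts), colnames(X)))
  covs <- vector("list", ngene)
  converged <- logical(ngene)
  alpha <- disp$alpha[rownames(cm$counts)]
  if (anyNA(alpha)) stop("dispersions missing for some genes")
  for (i in seq_len(ngene)) {
    f <- nb_irls(cm$counts[i, ], X, offset, alpha[[i]])
    beta[i, ] <- f$beta
    covs[[i]] <- f$cov
    converged[i] <- f$converged
  }
  base_mean <- rowMeans(normalize_counts(cm, sf))
  list(beta = beta, covs = covs, converged = converged,
       base_mean = base_mean, X = X, zone = zone)
}

contrast_vector <- function(X, ct) {
  L <- numeric(ncol(X))
  names(L) <- colnames(X)
  for (z in c(ct$zone_a, ct$zone_b)) {
    col <- paste0("zone", z)
    if (z != ZONES[1L]) {
      sgn <- if (z == ct$zone_a) 1 else -1
      L[col] <- L[col] + sgn
    }
  }
  L
}

de_table_from_fit <- function(fit, ct, fdr_threshold = 0.05) {
  L <- contrast_vector(fit$X, ct)
  ngene <- nrow(fit$beta)
  est <- drop(fit$beta %*% L)  # natural-log scale
  se <- vapply(seq_len(ngene), function(i) {
    v <- fit$covs[[i]]
    if (is.null(v)) NA_real_ else sqrt(drop(t(L) %*% v %*% L))
  }, numeric(1L))
  ok <- fit$converged & is.finite(est) & is.finite(se) & se > 0
  wald <- ifelse(ok, est / se, NA_real_)
  p <- ifelse(ok, 2 * stats::pnorm(-abs(wald)), NA_real_)
  n_bad <- sum(!ok)
  if (n_bad > 0)
    message(n_bad, " gene(s) failed to converge for contrast ",
            contrast_label(ct), "; excluded from FDR adjustment")
  fdr <- bh_adjust(p)
  tab <- data.frame(
    gene_id = rownames(fit$beta),
    base_mean = unname(fit$base_mean),
    log2fc = ifelse(ok, est / log(2), NA_real_),
    se = ifelse(ok, se / log(2), NA_real_),
    wald = wald, p = p, fdr = fdr,
    called = !is.na(fdr) & fdr <= fdr_threshold,
    stringsAsFactors = FALSE)
  attr(tab, "contrast") <- contrast_label(ct)
  tab
}

#' Per-gene differential expression for one zone contrast
#'
#' Fits, per gene, a negative-binomial log-link GLM with additive block and
#' zone effects and log size factors as fixed offsets, then tests the
#' requested pairwise zone contrast with a Wald statistic (coefficient over
#' its standard error, two-sided normal p-value). Dispersions are fixed at
#' the shrunken estimates from [estimate_dispersions()]. Genes that fail to
#' converge are flagged, get missing p-values, and are excluded from the
#' FDR denominator.
#'
#' @param counts a [count_matrix()].
#' @param sf size factors from [estimate_size_factors()].
#' @param disp dispersions from [estimate_dispersions()].
#' @param contrast a [zone_contrast()].
#' @param fdr_threshold cutoff used to fill the `called` column.
#' @return Data frame with columns gene_id, base_mean, log2fc, se, wald, p,
#'   fdr, called; the contrast label is attached as attribute `contrast`.
#' @export
fit_de <- function(counts, sf, disp, contrast, fdr_threshold = 0.05) {
  fit <- nb_fit_all(counts, sf, disp)
  de_table_from_fit(fit, contrast, fdr_threshold)
}

#' @rdname fit_de
#' @param contrasts list of contrasts; defaults to all three zone pairs.
#' @return For `fit_de_all`, a named list of result tables (the model is
#'   fitted once per gene and shared across contrasts).
#' @export
fit_de_all <- function(counts, sf, disp, contrasts = all_contrasts(),
                       fdr_threshold = 0.05) {
  fit <- nb_fit_all(counts, sf, disp)
  out <- lapply(contrasts, function(ct)
    de_table_from_fit(fit, ct, fdr_threshold))
  names(out) <- vapply(contrasts, contrast_label, character(1L))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment over the non-missing p-values; missing entries stay
#' missing and do not enter the denominator.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call differentially expressed genes
#'
#' Genes whose FDR-adjusted p-value is at or below the threshold
#' (the cutoff is inclusive).
#'
#' @param tab result table from [fit_de()].
#' @param threshold FDR cutoff in (0, 1); default 0.05.
#' @return A [gene_set()] of the called genes (possibly empty contents are
#'   an error in `gene_set`, so an empty call returns a zero-row set via a
#'   plain list with `gene_ids = character(0)`).
#' @export
call_de <- function(tab, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  ids <- tab$gene_id[!is.na(tab$fdr) & tab$fdr <= threshold]
  message(length(ids), " genes called DE at FDR <= ", threshold)
  structure(list(name = paste0("DE_", attr(tab, "contrast")),
                 gene_ids = as.character(ids)),
            class = "gene_set")
}
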