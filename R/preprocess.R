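#' Counts per million
#'
#' @param counts non-negative genes x samples count matrix.
#' @return matrix of the same shape whose columns each sum to 1e6.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  libs <- colSums(counts)
  zero <- libs == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts, 2, libs, "/") * 1e6
}

#' Filter lowly expressed genes
#'
#' Removes a gene when its CPM falls below `threshold` in at least
#' `ceiling(fraction * n_samples)` samples (the strict reading of
#' "CPM < 1 in 80% of the samples"). Gene order is preserved.
#'
#' @param counts genes x samples count matrix.
#' @param threshold CPM threshold (default 1).
#' @param fraction fraction of samples that must be below threshold for
#'   removal, in (0, 1].
#' @return the surviving subset of `counts`.
#' @export
filter_low_expression <- function(counts, threshold = 1, fraction = 0.8) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  x <- cpm(counts)
  n_low <- rowSums(x < threshold)
  keep <- n_low < ceiling(fraction * ncol(counts))
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across reference genes
#' (genes with nonzero counts in every sample) of the ratio of the sample's
#' count to the gene's geometric mean. Size factors are rescaled so their
#' geometric mean is 1.
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of positive size factors.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has nonzero counts in every sample; ",
         "filter lowly expressed genes first")
  lg <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Variance-stabilizing log transform
#'
#' Applies `log2(count / size_factor + 1)`, a monotone transform of
#' depth-normalized counts. This is a deliberately simple stand-in for a
#' fitted-dispersion variance-stabilizing transform: every downstream method
#' in the package depends only on a monotone, roughly variance-stabilized
#' log-like scale, not on the exact transform.
#'
#' @param counts genes x samples count matrix.
#' @param size_factors positive per-sample scaling, e.g. from
#'   [estimate_size_factors()]; defaults to all 1.
#' @return normalized real matrix with attributes `size_factors`.
#' @export
vst_transform <- function(counts, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(size_factors)) size_factors <- rep(1, ncol(counts))
  if (any(size_factors <= 0)) stop("size factors must be positive")
  out <- log2(sweep(counts, 2, size_factors, "/") + 1)
  attr(out, "size_factors") <- size_factors
  out
}

#' Filter genes with low dispersion
#'
#' Per-gene dispersion is the coefficient of variation of the normalized
#' values; genes strictly below the `quantile` quantile of the dispersion
#' distribution are removed.
#'
#' @param norm normalized genes x samples matrix.
#' @param quantile quantile cutoff in \[0, 1) (default 0.2, i.e. the lowest
#'   20% of dispersions are dropped).
#' @return surviving subset of `norm`.
#' @export
filter_low_dispersion <- function(norm, quantile = 0.2) {
  if (quantile == 0) return(norm)
  m <- rowMeans(norm)
  s <- apply(norm, 1, stats::sd)
  cv <- ifelse(m == 0, 0, s / m)
  if (length(unique(cv)) == 1) {
    warning("all genes have identical dispersion; none removed")
    return(norm)
  }
  cut <- stats::quantile(cv, quantile, names = FALSE)
  norm[cv >= cut, , drop = FALSE]
}

#' Remove an additive covariate effect from normalized expression
#'
#' Per gene, replaces the expression with the ordinary-least-squares residual
#' on the covariate indicator plus the grand mean, so that covariate groups
#' have equal per-gene means afterwards.
#'
#' @param norm normalized genes x samples matrix.
#' @param metadata sample metadata data.frame with a `sample` column.
#' @param covariate name of the metadata column to remove (default "sex").
#' @return adjusted matrix of the same shape.
#' @export
adjust_covariate <- function(norm, metadata, covariate = "sex") {
  meta <- metadata[match(colnames(norm), metadata$sample), ]
  v <- factor(meta[[covariate]])
  if (anyNA(v)) stop("covariate undefined for some samples")
  if (nlevels(v) < 2) {
    warning("covariate has a single level; no adjustment performed")
    return(norm)
  }
  X <- stats::model.matrix(~v)
  H <- X %*% solve(crossprod(X), t(X))
  fitted <- norm %*% t(H)
  res <- norm - fitted
  out <- res + rowMeans(norm)
  dimnames(out) <- dimnames(norm)
  out
}

#' Filter and normalize counts under the pooled or per-tissue strategy
#'
#' Strategy `"pooled"` filters and normalizes all samples of all tissues
#' together (the input for tissue-specificity, RIF and the tissue-to-tissue
#' network). Strategy `"per_tissue"` processes each tissue's samples
#' separately and additionally removes low-dispersion genes (the input for
#' differential co-expression and differential connectivity).
#'
#' @param counts genes x samples count matrix.
#' @param metadata sample metadata with `sample` and `tissue` columns.
#' @param strategy `"pooled"` or `"per_tissue"`.
#' @param cpm_threshold,cpm_fraction low-expression filter parameters.
#' @param dispersion_quantile low-dispersion filter quantile (per-tissue
#'   strategy only).
#' @param adjust_sex if TRUE, remove the additive sex effect after
#'   normalization.
#' @return for `"pooled"`, a normalized matrix; for `"per_tissue"`, a named
#'   list of normalized matrices, one per tissue.
#' @export
normalize_counts <- function(counts, metadata,
                             strategy = c("pooled", "per_tissue"),
                             cpm_threshold = 1, cpm_fraction = 0.8,
                             dispersion_quantile = 0.2,
                             adjust_sex = FALSE) {
  strategy <- match.arg(strategy)
  one <- function(cts, meta, disp) {
    cts <- filter_low_expression(cts, cpm_threshold, cpm_fraction)
    sf <- estimate_size_factors(cts)
    norm <- vst_transform(cts, sf)
    if (disp > 0) norm <- filter_low_dispersion(norm, disp)
    if (adjust_sex) norm <- adjust_covariate(norm, meta, "sex")
    attr(norm, "strategy") <- strategy
    norm
  }
  if (strategy == "pooled") {
    one(counts, metadata, 0)
  } else {
    tissues <- unique(metadata$tissue)
    out <- lapply(tissues, function(tt) {
      s <- metadata$sample[metadata$tissue == tt]
      one(counts[, s, drop = FALSE], metadata, dispersion_quantile)
    })
    stats::setNames(out, tissues)
  }
}
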