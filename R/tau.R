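#' Per-tissue mean expression profiles
#'
#' Arithmetic mean of normalized expression per gene and tissue. Negative
#' normalized values (possible under some transforms) are clipped to zero so
#' that the Tau index stays in \[0, 1\].
#'
#' @param norm normalized genes x samples matrix (pooled strategy).
#' @param metadata sample metadata with `sample` and `tissue` columns.
#' @return genes x tissues matrix of mean expression.
#' @export
tissue_means <- function(norm, metadata) {
  meta <- metadata[match(colnames(norm), metadata$sample), ]
  if (anyNA(meta$tissue)) stop("samples missing from metadata")
  tissues <- unique(metadata$tissue)
  out <- sapply(tissues, function(tt) {
    s <- meta$tissue == tt
    if (!any(s)) stop("no samples for tissue ", tt)
    rowMeans(norm[, s, drop = FALSE])
  })
  out[out < 0] <- 0
  out
}

#' Tau tissue-specificity index
#'
#' For a profile of per-tissue mean expression `x`,
#' `tau = sum(1 - x / max(x)) / (n - 1)` where `n` is the number of tissues.
#' Tau is 0 for uniform expression and 1 for single-tissue expression; it is
#' invariant to positive rescaling of the profile.
#'
#' @param profile numeric vector of non-negative per-tissue means (length
#'   >= 2).
#' @return tau in \[0, 1\], or `NA` for an all-zero profile.
#' @export
tau_index <- function(profile) {
  n <- length(profile)
  if (n < 2) stop("tau requires at least two tissues")
  mx <- max(profile)
  if (mx <= 0) return(NA_real_)
  sum(1 - profile / mx) / (n - 1)
}

#' Tau table for all genes
#'
#' @param means genes x tissues matrix from [tissue_means()].
#' @param cutoff tissue-specificity call threshold (default 0.8, inclusive).
#' @return data.frame with gene, per-tissue means, `tau`, `home_tissue`
#'   (argmax tissue, ties broken by column order) and `is_ts`.
#' @export
tau_table <- function(means, cutoff = 0.8) {
  tau <- apply(means, 1, tau_index)
  home <- colnames(means)[apply(means, 1, which.max)]
  home[is.na(tau)] <- NA_character_
  out <- data.frame(gene = rownames(means), means, tau = tau,
                    home_tissue = home,
                    is_ts = !is.na(tau) & tau >= cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Call tissue-specific genes
#'
#' @param tau_tab data.frame from [tau_table()].
#' @param cutoff tau threshold (inclusive).
#' @return the tissue-specific subset, sorted by decreasing tau.
#' @export
call_tissue_specific <- function(tau_tab, cutoff = 0.8) {
  ts <- tau_tab[!is.na(tau_tab$tau) & tau_tab$tau >= cutoff, , drop = FALSE]
  ts[order(-ts$tau, ts$gene), , drop = FALSE]
}
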