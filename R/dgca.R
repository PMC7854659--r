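#' Fisher z test for a difference between two correlations
#'
#' `dz = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, compared to a
#' standard normal (two-sided). Correlations of magnitude 1 are clamped to
#' 1 - 1e-12 with a warning.
#'
#' @param r1,r2 Pearson correlations (vectorized).
#' @param n1,n2 sample sizes (>= 4).
#' @return list with `dz` and `p`.
#' @export
fisher_z_diff <- function(r1, n1, r2, n2) {
  if (any(n1 < 4) || any(n2 < 4)) stop("need at least 4 samples per group")
  clamp <- function(r) {
    if (any(abs(r) >= 1)) {
      warning("correlation(s) of magnitude 1 clamped")
      r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    }
    r
  }
  r1 <- clamp(r1); r2 <- clamp(r2)
  dz <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(dz = dz, p = 2 * stats::pnorm(-abs(dz)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p numeric vector of p-values.
#' @return step-up BH q-values.
#' @export
adjust_fdr <- function(p) stats::p.adjust(p, method = "BH")

# two-sided p-value of a Pearson correlation via the t distribution
.cor_p <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Differential correlation class of a gene pair
#'
#' Each condition is mapped to `+`, `-` or `0` from the sign of its
#' correlation and whether its correlation p-value passes `alpha_within`;
#' the class is the composite `"con/res"` label (e.g. `"+/-"`, `"0/+"`).
#' `"0/0"` pairs are reported but conventionally excluded from the eight
#' differential-correlation classes.
#'
#' @param r_con,r_res per-condition correlations (vectorized).
#' @param p_con,p_res per-condition correlation p-values.
#' @param alpha_within within-condition significance level (default 0.05).
#' @return character vector of class labels.
#' @export
classify_pair <- function(r_con, p_con, r_res, p_res, alpha_within = 0.05) {
  lab <- function(r, p) ifelse(p <= alpha_within,
                               ifelse(r > 0, "+", "-"), "0")
  paste(lab(r_con, p_con), lab(r_res, p_res), sep = "/")
}

#' Differential co-expression analysis for one tissue
#'
#' Tests every unordered gene pair for a change in Pearson correlation
#' between the two conditions with the Fisher z statistic, adjusts the
#' p-values by Benjamini-Hochberg, and assigns the sign/significance
#' correlation class. Optionally the pair universe is restricted post hoc to
#' pairs touching at least one gene of interest (the treatment used for
#' high-dimensional tissues). A permutation mode (condition labels permuted
#' within the tissue) provides empirical p-values at small sample sizes,
#' where the normal approximation to the Fisher z statistic is
#' anti-conservative.
#'
#' @param norm normalized genes x samples matrix for one tissue.
#' @param metadata sample metadata with `sample` and `condition` columns.
#' @param genes optional subset of genes to test (default: all rows).
#' @param restrict_to optional character vector; keep only pairs with at
#'   least one endpoint in it.
#' @param alpha_within per-condition significance level for the class labels.
#' @param permute number of label permutations for empirical p-values
#'   (0 = analytic normal p-values, the default).
#' @param conditions length-2 vector, reference condition first.
#' @param seed seed for the permutation mode.
#' @return data.frame of class `"dc_pairs"`: `geneA`, `geneB`, `r_con`,
#'   `r_res`, `p_con`, `p_res`, `dz`, `p_diff`, `q_diff`, `class`.
#' @export
dc_analysis <- function(norm, metadata, genes = NULL, restrict_to = NULL,
                        alpha_within = 0.05, permute = 0,
                        conditions = c("CON", "RES"), seed = 1L) {
  meta <- metadata[match(colnames(norm), metadata$sample), ]
  if (anyNA(meta$condition))
    stop("condition undefined: samples missing from metadata")
  if (!is.null(genes)) norm <- norm[intersect(genes, rownames(norm)), ,
                                    drop = FALSE]
  s_con <- meta$condition == conditions[1]
  s_res <- meta$condition == conditions[2]
  if (!any(s_con) || !any(s_res)) stop("both conditions must be present")
  n1 <- sum(s_con); n2 <- sum(s_res)
  if (n1 < 4 || n2 < 4) stop("need at least 4 samples per condition")

  cmat <- function(s) {
    r <- suppressWarnings(stats::cor(t(norm[, s, drop = FALSE])))
    r[!is.finite(r)] <- 0
    r
  }
  r_con <- cmat(s_con)
  r_res <- cmat(s_res)
  ut <- upper.tri(r_con)
  ij <- which(ut, arr.ind = TRUE)
  gA <- rownames(norm)[ij[, 1]]
  gB <- rownames(norm)[ij[, 2]]
  out <- data.frame(
    geneA = pmin(gA, gB), geneB = pmax(gA, gB),
    r_con = r_con[ut], r_res = r_res[ut],
    n_con = n1, n_res = n2, stringsAsFactors = FALSE
  )
  if (!is.null(restrict_to)) {
    keep <- out$geneA %in% restrict_to | out$geneB %in% restrict_to
    out <- out[keep, , drop = FALSE]
  }
  out$p_con <- .cor_p(out$r_con, n1)
  out$p_res <- .cor_p(out$r_res, n2)
  fz <- fisher_z_diff(out$r_con, n1, out$r_res, n2)
  out$dz <- fz$dz
  out$p_diff <- fz$p

  if (permute > 0) {
    set.seed(seed)
    obs <- abs(out$dz)
    exceed <- numeric(length(obs))
    labels <- c(which(s_con), which(s_res))
    for (b in seq_len(permute)) {
      perm <- sample(labels)
      pc <- perm[seq_len(n1)]
      pr <- perm[n1 + seq_len(n2)]
      rc <- suppressWarnings(stats::cor(t(norm[, pc, drop = FALSE])))
      rr <- suppressWarnings(stats::cor(t(norm[, pr, drop = FALSE])))
      rc[!is.finite(rc)] <- 0; rr[!is.finite(rr)] <- 0
      dzb <- fisher_z_diff(rc[ut], n1, rr[ut], n2)$dz
      if (!is.null(restrict_to)) dzb <- dzb[keep]
      exceed <- exceed + (abs(dzb) >= obs)
    }
    out$p_diff <- (exceed + 1) / (permute + 1)
  }
  out$q_diff <- adjust_fdr(out$p_diff)
  out$class <- classify_pair(out$r_con, out$p_con, out$r_res, out$p_res,
                             alpha_within)
  rownames(out) <- NULL
  class(out) <- c("dc_pairs", "data.frame")
  out
}

#' Differential co-expression degree and hub calls
#'
#' Counts, per gene, its significant differentially co-expressed partners
#' and calls hubs with the shared mean + 2 SD degree rule.
#'
#' @param pairs `"dc_pairs"` data.frame from [dc_analysis()].
#' @param q_cutoff significance cutoff on `q_diff` (default 0.05).
#' @param sd_mult hub rule multiplier (default 2).
#' @return list with `degree` (named vector over genes appearing in
#'   significant pairs) and `hubs`.
#' @export
dc_hubs <- function(pairs, q_cutoff = 0.05, sd_mult = 2) {
  sig <- pairs[pairs$q_diff <= q_cutoff, , drop = FALSE]
  if (nrow(sig) == 0) return(list(degree = numeric(0), hubs = character(0)))
  deg <- table(c(sig$geneA, sig$geneB))
  deg <- stats::setNames(as.numeric(deg), names(deg))
  hubs <- if (length(deg) >= 3) call_hubs(deg, sd_mult) else character(0)
  list(degree = deg, hubs = hubs)
}
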