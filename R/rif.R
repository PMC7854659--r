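#' Condition-wise TF--target correlations and target summaries
#'
#' Computes, within one tissue, the Pearson correlation of every
#' (transcription factor, target) pair separately in each condition, plus the
#' per-target expression summaries that feed the regulatory impact factors:
#' mean expression per condition, average abundance, differential expression
#' and the phenotypic impact factor PIF = abundance x differential expression.
#'
#' @param norm normalized genes x samples matrix restricted to one tissue.
#' @param metadata sample metadata with `sample` and `condition` columns.
#' @param tfs,targets character vectors of gene ids present in `norm`.
#' @param conditions length-2 character vector; first entry is the reference
#'   (control) condition.
#' @return list with `con`, `res` (TF x target correlation matrices) and
#'   `targets` (data.frame of per-target summaries). Zero-variance genes get
#'   correlation 0 with a warning.
#' @export
condition_correlations <- function(norm, metadata, tfs, targets,
                                   conditions = c("CON", "RES")) {
  meta <- metadata[match(colnames(norm), metadata$sample), ]
  missing <- setdiff(c(tfs, targets), rownames(norm))
  if (length(missing))
    stop("genes absent from matrix: ", paste(missing, collapse = ", "))
  cor_cond <- function(cond) {
    s <- meta$condition == cond
    if (!any(s)) stop("condition absent: ", cond)
    if (sum(s) < 4) stop("need at least 4 samples per condition")
    xt <- t(norm[tfs, s, drop = FALSE])
    yt <- t(norm[targets, s, drop = FALSE])
    sd0 <- c(apply(xt, 2, stats::sd), apply(yt, 2, stats::sd)) == 0
    if (any(sd0))
      warning("zero-variance gene(s) in condition ", cond,
              "; correlations set to 0")
    r <- suppressWarnings(stats::cor(xt, yt))
    r[!is.finite(r)] <- 0
    r
  }
  s_con <- meta$condition == conditions[1]
  s_res <- meta$condition == conditions[2]
  if (!any(s_con) || !any(s_res))
    stop("both conditions must be present")
  e_con <- rowMeans(norm[targets, s_con, drop = FALSE])
  e_res <- rowMeans(norm[targets, s_res, drop = FALSE])
  list(
    con = cor_cond(conditions[1]),
    res = cor_cond(conditions[2]),
    targets = data.frame(
      target = targets, e_con = e_con, e_res = e_res,
      abundance = (e_con + e_res) / 2, de = e_con - e_res,
      pif = (e_con + e_res) / 2 * (e_con - e_res),
      stringsAsFactors = FALSE, row.names = NULL
    )
  )
}

#' Regulatory impact factors (RIF1 and RIF2)
#'
#' With differential wiring `dw_ij = r_con[i,j] - r_res[i,j]` for TF i and
#' target j,
#' \deqn{RIF1_i = \frac{1}{n_t}\sum_j PIF_j \, dw_{ij}^2}
#' \deqn{RIF2_i = \frac{1}{n_t}\sum_j (e_{con,j} r_{con,ij})^2 -
#'   (e_{res,j} r_{res,ij})^2}
#' RIF1 highlights regulators whose wiring to high-impact targets changes
#' between conditions; RIF2 scores the change in a TF's squared
#' expression-weighted ability to predict target abundance. Raw scores are
#' z-standardized over the TFs and a TF is called significant when either
#' |z| exceeds the two-sided normal quantile at `alpha`.
#'
#' @param cc output of [condition_correlations()].
#' @param alpha two-sided significance level on the z-scores (default 0.01).
#' @return data.frame with raw and z scores per TF and the significance call,
#'   of class `"rif_result"`.
#' @export
rif_scores <- function(cc, alpha = 0.01) {
  n_t <- nrow(cc$targets)
  if (n_t == 0) stop("no targets")
  dw <- cc$con - cc$res
  rif1 <- as.numeric(dw^2 %*% cc$targets$pif) / n_t
  w_con <- sweep(cc$con, 2, cc$targets$e_con, "*")^2
  w_res <- sweep(cc$res, 2, cc$targets$e_res, "*")^2
  rif2 <- rowSums(w_con - w_res) / n_t
  zs <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  z1 <- zs(rif1)
  z2 <- zs(rif2)
  zcrit <- stats::qnorm(1 - alpha / 2)
  out <- data.frame(
    tf = rownames(cc$con), rif1_raw = rif1, rif1_z = z1,
    rif2_raw = rif2, rif2_z = z2,
    significant = abs(z1) >= zcrit | abs(z2) >= zcrit,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("rif_result", "data.frame")
  out
}

#' Rank regulators by extremeness of their RIF z-scores
#'
#' @param rif data.frame from [rif_scores()].
#' @return the same rows sorted by `max(|rif1_z|, |rif2_z|)` descending, ties
#'   broken by gene id; adds a `rank` column.
#' @export
rank_regulators <- function(rif) {
  score <- pmax(abs(rif$rif1_z), abs(rif$rif2_z))
  out <- rif[order(-score, rif$tf), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' One-call RIF analysis for a tissue
#'
#' @inheritParams condition_correlations
#' @inheritParams rif_scores
#' @return ranked [rif_scores()] table.
#' @export
rif_analysis <- function(norm, metadata, tfs, targets, alpha = 0.01,
                         conditions = c("CON", "RES")) {
  tfs <- intersect(tfs, rownames(norm))
  targets <- setdiff(intersect(targets, rownames(norm)), tfs)
  if (!length(tfs)) stop("no TFs present in the matrix")
  if (!length(targets)) stop("no targets present in the matrix")
  cc <- condition_correlations(norm, metadata, tfs, targets, conditions)
  rank_regulators(rif_scores(cc, alpha))
}
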