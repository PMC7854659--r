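#' First-order partial correlation
#'
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`:
#' the correlation between x and y after conditioning on z. Undefined
#' (returned as `NA`) when a flanking correlation has magnitude 1.
#'
#' @param r_xy,r_xz,r_yz pairwise Pearson correlations (vectorized).
#' @return partial correlation value(s).
#' @export
first_order_partial <- function(r_xy, r_xz, r_yz) {
  den <- (1 - r_xz^2) * (1 - r_yz^2)
  out <- ifelse(den > 0, (r_xy - r_xz * r_yz) / sqrt(den), NA_real_)
  out
}

#' Pearson correlation matrix of a normalized expression submatrix
#'
#' @param norm normalized genes x samples matrix (>= 4 samples).
#' @return symmetric gene x gene correlation matrix with unit diagonal.
#'   Zero-variance genes are excluded with a warning.
#' @export
pearson_matrix <- function(norm) {
  if (ncol(norm) < 4) stop("need at least 4 samples")
  sds <- apply(norm, 1, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance gene(s): ",
            paste(utils::head(rownames(norm)[sds == 0], 5), collapse = ", "))
    norm <- norm[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(norm))
  r[lower.tri(r)] <- t(r)[lower.tri(r)]   # exact symmetry
  diag(r) <- 1
  r
}

#' PCIT significance mask
#'
#' Runs the partial correlation and information theory (PCIT) algorithm: for
#' every gene trio the three first-order partial correlations define a local
#' tolerance (the mean of the signed ratios partial/direct), and the
#' association between two genes is deemed non-significant if, for some third
#' gene, its magnitude falls below the tolerance times both flanking
#' correlations. Pairs surviving every trio form the mask. With fewer than
#' 3 genes every pair is retained (no third gene exists to eliminate it).
#'
#' Near-zero direct correlations (|r| < 1e-12) get a tolerance ratio of 1
#' (maximal redundancy), and a flanking correlation of magnitude 1 eliminates
#' the pair outright; both guards avoid division blow-ups.
#'
#' @param corr symmetric correlation matrix.
#' @return symmetric logical matrix; `TRUE` marks significant pairs
#'   (diagonal is `FALSE`).
#' @seealso [pcit_ref()] for the brute-force reference implementation.
#' @export
pcit <- function(corr) {
  if (!isSymmetric(unname(corr)))
    stop("correlation matrix must be symmetric")
  n <- nrow(corr)
  keep <- matrix(TRUE, n, n, dimnames = dimnames(corr))
  diag(keep) <- FALSE
  if (n < 3) return(keep)
  elim <- pcit_elim_cpp(corr)
  keep[elim] <- FALSE
  keep
}

#' Brute-force PCIT reference implementation
#'
#' Naive O(n^3) triple loop over all gene trios, written with scalar
#' arithmetic and [first_order_partial()]. Intended as an independent oracle
#' for [pcit()]; the two must return identical masks.
#'
#' @inheritParams pcit
#' @return symmetric logical significance mask.
#' @export
pcit_ref <- function(corr) {
  if (!isSymmetric(unname(corr)))
    stop("correlation matrix must be symmetric")
  n <- nrow(corr)
  keep <- matrix(TRUE, n, n, dimnames = dimnames(corr))
  diag(keep) <- FALSE
  if (n < 3) return(keep)
  tiny <- 1e-12
  ratio <- function(p, r) if (!is.na(p) && abs(r) >= tiny) p / r else 1
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    rxy <- corr[x, y]; rxz <- corr[x, z]; ryz <- corr[y, z]
    pxy <- first_order_partial(rxy, rxz, ryz)
    pxz <- first_order_partial(rxz, rxy, ryz)
    pyz <- first_order_partial(ryz, rxy, rxz)
    eps <- (ratio(pxy, rxy) + ratio(pxz, rxz) + ratio(pyz, ryz)) / 3
    if (is.na(pxy) ||
        (abs(rxy) <= abs(eps * rxz) && abs(rxy) <= abs(eps * ryz)))
      keep[x, y] <- keep[y, x] <- FALSE
    if (is.na(pxz) ||
        (abs(rxz) <= abs(eps * rxy) && abs(rxz) <= abs(eps * ryz)))
      keep[x, z] <- keep[z, x] <- FALSE
    if (is.na(pyz) ||
        (abs(ryz) <= abs(eps * rxy) && abs(ryz) <= abs(eps * rxz)))
      keep[y, z] <- keep[z, y] <- FALSE
  }
  keep
}
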