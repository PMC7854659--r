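#' Build a PCIT co-expression network
#'
#' Computes the Pearson correlation matrix of the selected genes, keeps the
#' PCIT-significant pairs, and retains as edges those with |r| strictly
#' greater than `min_abs_r` (by default the raw correlation is thresholded;
#' set `threshold_on = "partial"` to threshold the minimum absolute partial
#' correlation instead). Optionally an edge is kept only when at least one
#' endpoint carries a flag (the rule used for condition-specific networks,
#' where an endpoint must be a DEG or TF).
#'
#' @param norm normalized genes x samples matrix.
#' @param genes character vector of genes to use (default: all rows).
#' @param min_abs_r edge threshold on |r| (default 0.9, strict).
#' @param node_attrs optional data.frame with a `gene` column plus logical
#'   flag columns (e.g. `is_deg`, `is_ts`, `is_tf`) and/or a `tissue` column
#'   (tissue of maximal expression, used for display).
#' @param require_flag character vector of `node_attrs` columns; if given, an
#'   edge is retained only when at least one endpoint has one of these flags
#'   set.
#' @param threshold_on `"raw"` or `"partial"`.
#' @return object of class `"coexnet"`: list with `nodes` (data.frame of
#'   node attributes and degree) and `edges` (data.frame `from`, `to`,
#'   `weight`, endpoints sorted within and across rows).
#' @export
build_network <- function(norm, genes = NULL, min_abs_r = 0.9,
                          node_attrs = NULL, require_flag = NULL,
                          threshold_on = c("raw", "partial")) {
  threshold_on <- match.arg(threshold_on)
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(norm))
    if (!length(genes)) stop("empty gene subset")
    norm <- norm[genes, , drop = FALSE]
  }
  r <- pearson_matrix(norm)
  keep <- pcit(r)
  if (threshold_on == "partial" && nrow(r) >= 3) {
    pmin_abs <- .min_abs_partial(r)
    strong <- pmin_abs > min_abs_r
  } else {
    strong <- abs(r) > min_abs_r
  }
  adj <- keep & strong
  ij <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(r)[ij[, 1]], to = rownames(r)[ij[, 2]],
    weight = r[ij], stringsAsFactors = FALSE
  )
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- data.frame(gene = rownames(r), stringsAsFactors = FALSE)
  if (!is.null(node_attrs))
    nodes <- merge(nodes, node_attrs, by = "gene", all.x = TRUE,
                   sort = TRUE)
  if (!is.null(require_flag)) {
    flag <- rep(FALSE, nrow(nodes))
    for (f in require_flag) {
      v <- nodes[[f]]
      if (is.null(v)) stop("missing node flag column: ", f)
      flag <- flag | (!is.na(v) & v)
    }
    names(flag) <- nodes$gene
    keep_edge <- flag[edges$from] | flag[edges$to]
    edges <- edges[keep_edge, , drop = FALSE]
    rownames(edges) <- NULL
  }
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$gene))
  nodes$degree <- as.integer(deg[nodes$gene])
  structure(
    list(nodes = nodes, edges = edges,
         params = list(min_abs_r = min_abs_r, threshold_on = threshold_on,
                       require_flag = require_flag)),
    class = "coexnet"
  )
}

# Minimum |partial correlation| over all conditioning genes, per pair.
.min_abs_partial <- function(r) {
  n <- nrow(r)
  out <- abs(r)
  for (z in seq_len(n)) {
    a <- r[, z]
    den <- sqrt(outer(1 - a^2, 1 - a^2))
    p <- abs((r - outer(a, a)) / den)
    p[, z] <- Inf; p[z, ] <- Inf
    diag(p) <- Inf
    p[!is.finite(p)] <- 0
    out <- pmin(out, p)
  }
  diag(out) <- 0
  out
}

#' Convert a coexnet to an igraph graph
#'
#' @param net `"coexnet"` object.
#' @return undirected [igraph::graph] with `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' @export
print.coexnet <- function(x, ...) {
  cat(sprintf("Co-expression network: %d nodes, %d edges (|r| > %s)\n",
              nrow(x$nodes), nrow(x$edges), x$params$min_abs_r))
  invisible(x)
}

#' Network topology statistics
#'
#' Per-node degree, global average local clustering coefficient (triangles
#' over connected triples, 0 for nodes of degree < 2), average degree overall
#' and per node group, and the scale-free fit R-squared.
#'
#' @param net `"coexnet"` object.
#' @param group optional name of a `nodes` column to average degree by
#'   (e.g. `"tissue"`).
#' @return list of class `"coexnet_stats"` with `degree`, `clustering`,
#'   `avg_degree`, `avg_degree_by_group`, `scale_free_r2`.
#' @export
network_stats <- function(net, group = NULL) {
  if (nrow(net$nodes) == 0) stop("empty network")
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  cc_local <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc_local[is.na(cc_local)] <- 0
  by_group <- NULL
  if (!is.null(group) && !is.null(net$nodes[[group]]))
    by_group <- tapply(deg[net$nodes$gene], net$nodes[[group]], mean)
  structure(
    list(degree = deg, clustering = mean(cc_local), avg_degree = mean(deg),
         avg_degree_by_group = by_group,
         scale_free_r2 = scale_free_fit(deg)),
    class = "coexnet_stats"
  )
}

#' @export
print.coexnet_stats <- function(x, ...) {
  cat(sprintf("degree: mean %.2f, max %d | clustering %.3f | scale-free R2 %s\n",
              x$avg_degree, max(x$degree), x$clustering,
              ifelse(is.na(x$scale_free_r2), "NA",
                     sprintf("%.3f", x$scale_free_r2))))
  invisible(x)
}

#' Call hub genes from a degree distribution
#'
#' Hubs are nodes whose degree is at least `mean + sd_mult * sd` of the
#' degree distribution. A zero-variance degree distribution yields no hubs.
#'
#' @param degree named numeric vector of node degrees (or a
#'   `"coexnet_stats"` object).
#' @param sd_mult number of standard deviations above the mean (default 2).
#' @return character vector of hub gene ids.
#' @export
call_hubs <- function(degree, sd_mult = 2) {
  if (inherits(degree, "coexnet_stats")) degree <- degree$degree
  if (length(degree) < 3) stop("need at least 3 nodes")
  s <- stats::sd(degree)
  if (is.na(s) || s == 0) return(character(0))
  names(degree)[degree >= mean(degree) + sd_mult * s]
}

#' Scale-free topology fit
#'
#' Bins the positive degrees into their frequency distribution P(k) and
#' regresses log10 P(k) on log10 k; returns the coefficient of
#' determination. An exact power law gives R-squared 1.
#'
#' @param degree numeric vector of node degrees.
#' @return R-squared in \[0, 1\], or `NA` when fewer than 3 distinct positive
#'   degrees exist.
#' @export
scale_free_fit <- function(degree) {
  k <- degree[degree > 0]
  tab <- table(k)
  if (length(tab) < 3) return(NA_real_)
  kk <- as.numeric(names(tab))
  pk <- as.numeric(tab) / sum(tab)
  fit <- stats::lm(log10(pk) ~ log10(kk))
  # an exact power law is a valid input; lm's perfect-fit warning is noise
  suppressWarnings(summary(fit)$r.squared)
}
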