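#' Normalized connectivity
#'
#' Each gene's degree divided by the maximum degree of the network, so the
#' best-connected node has K = 1.
#'
#' @param net `"coexnet"` object with at least one edge.
#' @return named numeric vector of K values in \[0, 1\].
#' @export
normalized_connectivity <- function(net) {
  if (nrow(net$edges) == 0) stop("network has no edges")
  deg <- stats::setNames(net$nodes$degree, net$nodes$gene)
  deg / max(deg)
}

#' Differential connectivity (DK) between condition-specific networks
#'
#' For each gene in the union of the two node sets (every gene the networks
#' were inferred over, including unconnected ones),
#' `DK = K_con - K_res` with K the degree normalized by the network's maximum
#' degree ([normalized_connectivity()]). Genes absent from one network get
#' K = 0 there (they are maximally rewired) unless `drop_unshared = TRUE`
#' restricts scoring to genes present in both node sets.
#' DK is z-standardized over genes and called significant at `|z| >= z_crit`.
#'
#' @param net_con,net_res condition-specific `"coexnet"` networks.
#' @param z_crit significance threshold on |z| (default 1.96, p < 0.05).
#' @param drop_unshared if TRUE, only genes present in both networks are
#'   scored.
#' @param center if TRUE (default), subtract the mean DK before scaling by
#'   the standard deviation.
#' @return data.frame of class `"dk_result"`: `gene`, `k_con`, `k_res`,
#'   `dk`, `z`, `significant`.
#' @export
dk_scores <- function(net_con, net_res, z_crit = 1.96,
                      drop_unshared = FALSE, center = TRUE) {
  k_con <- normalized_connectivity(net_con)
  k_res <- normalized_connectivity(net_res)
  genes <- if (drop_unshared) intersect(names(k_con), names(k_res))
           else union(names(k_con), names(k_res))
  genes <- sort(genes)
  kc <- ifelse(genes %in% names(k_con), k_con[genes], 0)
  kr <- ifelse(genes %in% names(k_res), k_res[genes], 0)
  kc[is.na(kc)] <- 0; kr[is.na(kr)] <- 0
  dk <- kc - kr
  s <- stats::sd(dk)
  if (is.na(s) || s == 0) {
    warning("zero variance in DK; no significant genes")
    z <- rep(0, length(dk))
  } else {
    z <- (dk - if (center) mean(dk) else 0) / s
  }
  out <- data.frame(gene = genes, k_con = kc, k_res = kr, dk = dk, z = z,
                    significant = abs(z) >= z_crit,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("dk_result", "data.frame")
  out
}

#' Union ("central reference") network of two condition networks
#'
#' Node and edge union of the CON and RES networks; every node and edge is
#' tagged `"CON"`, `"RES"` or `"shared"` by provenance, the input expected by
#' rewiring visualisations.
#'
#' @param net_con,net_res condition-specific `"coexnet"` networks.
#' @return `"coexnet"` object whose `nodes` and `edges` carry a `provenance`
#'   column (edge weights from CON take precedence for shared edges).
#' @export
union_network <- function(net_con, net_res) {
  key <- function(e) paste(e$from, e$to, sep = "\r")
  e_con <- net_con$edges; e_res <- net_res$edges
  kc <- key(e_con); kr <- key(e_res)
  e_con$provenance <- if (nrow(e_con)) ifelse(kc %in% kr, "shared", "CON")
                      else character(0)
  e_res <- e_res[!(kr %in% kc), , drop = FALSE]
  e_res$provenance <- rep("RES", nrow(e_res))
  edges <- rbind(e_con, e_res)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  n_con <- net_con$nodes$gene[net_con$nodes$degree > 0]
  n_res <- net_res$nodes$gene[net_res$nodes$degree > 0]
  genes <- sort(union(n_con, n_res))
  nodes <- data.frame(
    gene = genes,
    provenance = ifelse(genes %in% n_con & genes %in% n_res, "shared",
                        ifelse(genes %in% n_con, "CON", "RES")),
    stringsAsFactors = FALSE
  )
  deg <- table(factor(c(edges$from, edges$to), levels = genes))
  nodes$degree <- as.integer(deg[nodes$gene])
  structure(list(nodes = nodes, edges = edges,
                 params = list(union_of = c("CON", "RES"))),
            class = "coexnet")
}

#' Connectivity gain summary between condition networks
#'
#' Cumulative degree distributions per condition plus edge/node totals and
#' the sign of the mean-degree difference (which condition gained
#' connectivity).
#'
#' @param net_con,net_res condition-specific `"coexnet"` networks.
#' @return list with `cdf` (data.frame: degree, cumulative fraction,
#'   condition), `totals`, `mean_degree_diff` (CON - RES) and `gain`
#'   (`"CON"`, `"RES"` or `"none"`).
#' @export
connectivity_gain <- function(net_con, net_res) {
  cdf_tab <- function(net, cond) {
    deg <- net$nodes$degree[net$nodes$degree > 0]
    if (!length(deg)) return(NULL)
    k <- sort(unique(deg))
    data.frame(degree = k, cum_frac = stats::ecdf(deg)(k),
               condition = cond, stringsAsFactors = FALSE)
  }
  mean_deg <- function(net) {
    d <- net$nodes$degree[net$nodes$degree > 0]
    if (!length(d)) 0 else mean(d)
  }
  diff <- mean_deg(net_con) - mean_deg(net_res)
  list(
    cdf = rbind(cdf_tab(net_con, "CON"), cdf_tab(net_res, "RES")),
    totals = data.frame(
      condition = c("CON", "RES"),
      nodes = c(sum(net_con$nodes$degree > 0), sum(net_res$nodes$degree > 0)),
      edges = c(nrow(net_con$edges), nrow(net_res$edges))
    ),
    mean_degree_diff = diff,
    gain = if (diff > 0) "CON" else if (diff < 0) "RES" else "none"
  )
}
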