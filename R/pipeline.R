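#' Run the full multi-tissue two-condition network pipeline
#'
#' Orchestrates the whole workflow on a count matrix: preprocessing under
#' both normalization strategies, tissue-specificity (Tau), regulatory impact
#' factors (RIF) per tissue, the PCIT tissue-to-tissue network over the
#' prioritized genes (DEG, TS and significant TFs), differential
#' co-expression per tissue, and condition-specific networks with
#' differential connectivity (DK) and the union network per tissue. With no
#' input data a synthetic dataset is simulated from `sim` first.
#'
#' @param counts genes x samples count matrix (NULL to simulate).
#' @param metadata sample metadata (`sample`, `tissue`, `condition`, `sex`).
#' @param deg character vector (or per-tissue named list) of differentially
#'   expressed genes -- an input, not computed here.
#' @param tfs transcription factor catalogue (character vector); if NULL the
#'   RIF stage is skipped with a warning and prioritization falls back to
#'   DEG and TS genes.
#' @param sim [sim_config()] used when `counts` is NULL.
#' @param thresholds named list overriding any of: `cpm = 1`,
#'   `cpm_fraction = 0.8`, `dispersion_quantile = 0.2`, `tau_cutoff = 0.8`,
#'   `rif_alpha = 0.01`, `min_abs_r = 0.9`, `dc_q = 0.05`,
#'   `dc_alpha_within = 0.05`, `dk_z = 1.96`, `hub_sd = 2`.
#' @param adjust_sex remove the additive sex effect after normalization.
#' @param out_dir optional directory; when given, all result tables, network
#'   exports and a JSON run manifest are written there.
#' @param seed seed forwarded to the simulation config.
#' @param verbose log each stage's input/output gene counts.
#' @return object of class `"fetonet"`; a list with elements `truth` (NULL
#'   for user data), `norm_pooled`, `norm_tissue`, `tau`, `ts`, `rif`,
#'   `network` (+ `network_stats`, `hubs`), `dc`, `dk`, `condition_networks`,
#'   `union_networks`, `gain`, `thresholds`.
#' @seealso [simulate_dataset()], [build_network()], [dc_analysis()],
#'   [dk_scores()]
#' @export
fetonet <- function(counts = NULL, metadata = NULL, deg = NULL, tfs = NULL,
                    sim = sim_config(seed = seed), thresholds = list(),
                    adjust_sex = FALSE, out_dir = NULL, seed = 1L,
                    verbose = TRUE) {
  th <- utils::modifyList(list(
    cpm = 1, cpm_fraction = 0.8, dispersion_quantile = 0.2,
    tau_cutoff = 0.8, rif_alpha = 0.01, min_abs_r = 0.9,
    dc_q = 0.05, dc_alpha_within = 0.05, dk_z = 1.96, hub_sd = 2
  ), thresholds)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  truth <- NULL
  if (is.null(counts)) {
    say("simulate: generating synthetic dataset (seed %d)", sim$seed)
    ds <- stage("simulate", simulate_dataset(sim))
    counts <- ds$counts; metadata <- ds$metadata; truth <- ds$truth
    if (is.null(deg)) deg <- truth$de_genes$gene
    if (is.null(tfs)) tfs <- truth$tf_genes
  }
  if (is.null(metadata)) stop("metadata required with user-supplied counts")
  deg_all <- unique(unlist(deg, use.names = FALSE))
  conditions <- unique(metadata$condition)
  tissues <- unique(metadata$tissue)

  say("preprocess: %d genes x %d samples in", nrow(counts), ncol(counts))
  norm1 <- stage("preprocess", normalize_counts(
    counts, metadata, "pooled", th$cpm, th$cpm_fraction,
    adjust_sex = adjust_sex
  ))
  norm2 <- stage("preprocess", normalize_counts(
    counts, metadata, "per_tissue", th$cpm, th$cpm_fraction,
    th$dispersion_quantile, adjust_sex = adjust_sex
  ))
  say("preprocess: pooled %d genes; per-tissue %s", nrow(norm1),
      paste(sprintf("%s=%d", names(norm2), vapply(norm2, nrow, 1L)),
            collapse = ", "))

  say("tau: scoring tissue specificity")
  means <- stage("tau", tissue_means(norm1, metadata))
  tau_tab <- stage("tau", tau_table(means, th$tau_cutoff))
  ts_tab <- call_tissue_specific(tau_tab, th$tau_cutoff)
  say("tau: %d TS genes at tau >= %.2f", nrow(ts_tab), th$tau_cutoff)

  rif <- NULL
  sig_tfs <- character(0)
  if (is.null(tfs)) {
    warning("no TF catalogue supplied; RIF stage skipped")
  } else {
    targets <- union(deg_all, ts_tab$gene)
    rif <- lapply(tissues, function(tt) {
      s <- metadata$sample[metadata$tissue == tt]
      stage("rif", rif_analysis(norm1[, s, drop = FALSE], metadata,
                                tfs, targets, th$rif_alpha, conditions))
    })
    names(rif) <- tissues
    sig_tfs <- unique(unlist(lapply(rif, function(r) r$tf[r$significant])))
    say("rif: %d significant TFs across tissues (p <= %s)",
        length(sig_tfs), th$rif_alpha)
  }

  prioritized <- unique(c(deg_all, ts_tab$gene, sig_tfs))
  prioritized <- intersect(prioritized, rownames(norm1))
  say("network: %d prioritized genes (DEG + TS + TF)", length(prioritized))
  attrs <- data.frame(
    gene = rownames(norm1),
    tissue = colnames(means)[apply(means, 1, which.max)],
    is_deg = rownames(norm1) %in% deg_all,
    is_ts = rownames(norm1) %in% ts_tab$gene,
    is_tf = rownames(norm1) %in% if (is.null(tfs)) character(0) else tfs,
    stringsAsFactors = FALSE
  )
  net <- stage("network", build_network(norm1, prioritized, th$min_abs_r,
                                        node_attrs = attrs))
  net_stats <- network_stats(net, group = "tissue")
  hubs <- call_hubs(net_stats, th$hub_sd)
  say("network: %d nodes, %d edges; clustering %.2f",
      sum(net$nodes$degree > 0), nrow(net$edges), net_stats$clustering)

  dc <- list(); dk <- list()
  cond_nets <- list(); union_nets <- list(); gain <- list()
  for (tt in tissues) {
    nt <- norm2[[tt]]
    say("dc[%s]: testing %d genes", tt, nrow(nt))
    dc[[tt]] <- stage("dc", dc_analysis(
      nt, metadata, alpha_within = th$dc_alpha_within,
      conditions = conditions
    ))
    say("dc[%s]: %d significant pairs (q <= %s)", tt,
        sum(dc[[tt]]$q_diff <= th$dc_q), th$dc_q)
    cn <- list()
    for (cond in conditions) {
      s <- metadata$sample[metadata$tissue == tt &
                             metadata$condition == cond]
      cn[[cond]] <- stage("dk", build_network(
        nt[, s, drop = FALSE], min_abs_r = th$min_abs_r, node_attrs = attrs,
        require_flag = c("is_deg", "is_tf")
      ))
    }
    cond_nets[[tt]] <- cn
    ok <- vapply(cn, function(x) nrow(x$edges) > 0, TRUE)
    if (all(ok)) {
      dk[[tt]] <- stage("dk", dk_scores(cn[[1]], cn[[2]], th$dk_z))
      union_nets[[tt]] <- union_network(cn[[1]], cn[[2]])
      gain[[tt]] <- connectivity_gain(cn[[1]], cn[[2]])
      say("dk[%s]: CON %d / RES %d edges; %d DK genes (|z| >= %s)", tt,
          nrow(cn[[1]]$edges), nrow(cn[[2]]$edges),
          sum(dk[[tt]]$significant), th$dk_z)
    } else {
      warning(sprintf("tissue %s: empty condition network; DK skipped", tt))
    }
  }

  res <- structure(list(
    counts = counts, metadata = metadata, truth = truth,
    norm_pooled = norm1, norm_tissue = norm2,
    tau = tau_tab, ts = ts_tab, rif = rif,
    network = net, network_stats = net_stats, hubs = hubs,
    dc = dc, dk = dk, condition_networks = cond_nets,
    union_networks = union_nets, gain = gain,
    thresholds = th, seed = seed
  ), class = "fetonet")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @rdname fetonet
#' @param ... forwarded to [fetonet()].
#' @export
run_all <- function(...) fetonet(...)

#' Write all pipeline result tables to a directory
#'
#' Emits TSV tables for counts, metadata, Tau, RIF, DC and DK results,
#' TSV + SIF exports of every network, ground-truth tables when available,
#' and a JSON manifest (package version, seed, thresholds, stage row counts)
#' sufficient to reproduce the run.
#'
#' @param res `"fetonet"` object.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_counts(res$counts, file.path(dir, "counts.tsv"))
  wt(res$metadata, "samples.tsv")
  if (!is.null(res$truth))
    write_truth(res$truth, dir, genes = rownames(res$counts))
  wt(res$tau, "tau.tsv")
  wt(res$ts, "ts_genes.tsv")
  if (!is.null(res$rif)) {
    rif_df <- do.call(rbind, lapply(names(res$rif), function(tt)
      cbind(tissue = tt, res$rif[[tt]], stringsAsFactors = FALSE)))
    wt(rif_df, "rif.tsv")
  }
  export_network(res$network, dir, "t2t_network")
  for (tt in names(res$dc)) wt(res$dc[[tt]], sprintf("dc_%s.tsv", tt))
  for (tt in names(res$dk)) wt(res$dk[[tt]], sprintf("dk_%s.tsv", tt))
  for (tt in names(res$condition_networks)) {
    cn <- res$condition_networks[[tt]]
    for (cond in names(cn))
      export_network(cn[[cond]], dir, sprintf("net_%s_%s", tt, cond))
  }
  for (tt in names(res$union_networks))
    export_network(res$union_networks[[tt]], dir,
                   sprintf("union_%s", tt))
  manifest <- list(
    package = "fetonet",
    version = as.character(utils::packageVersion("fetonet")),
    seed = res$seed,
    thresholds = res$thresholds,
    genes_in = nrow(res$counts), samples = ncol(res$counts),
    genes_pooled = nrow(res$norm_pooled),
    genes_per_tissue = lapply(res$norm_tissue, nrow),
    n_ts = nrow(res$ts),
    network_nodes = sum(res$network$nodes$degree > 0),
    network_edges = nrow(res$network$edges),
    dc_significant = lapply(res$dc, function(d)
      sum(d$q_diff <= res$thresholds$dc_q)),
    dk_significant = lapply(res$dk, function(d) sum(d$significant))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.fetonet <- function(x, ...) {
  cat("Multi-tissue two-condition co-expression analysis\n")
  cat(sprintf("  input: %d genes x %d samples (%d tissues)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$metadata$tissue))))
  cat(sprintf("  TS genes: %d (tau >= %.2f)\n", nrow(x$ts),
              x$thresholds$tau_cutoff))
  if (!is.null(x$rif))
    cat(sprintf("  significant TFs: %d\n",
                length(unique(unlist(lapply(x$rif, function(r)
                  r$tf[r$significant]))))))
  cat(sprintf("  tissue-to-tissue network: %d nodes, %d edges\n",
              sum(x$network$nodes$degree > 0), nrow(x$network$edges)))
  for (tt in names(x$dk))
    cat(sprintf("  %s: %d DC pairs (q <= %.2f), %d DK genes\n", tt,
                sum(x$dc[[tt]]$q_diff <= x$thresholds$dc_q),
                x$thresholds$dc_q, sum(x$dk[[tt]]$significant)))
  invisible(x)
}

#' @export
summary.fetonet <- function(object, ...) {
  x <- object
  df <- data.frame(
    tissue = names(x$dc),
    genes_tested = vapply(names(x$dc), function(tt)
      nrow(x$norm_tissue[[tt]]), 1L),
    dc_pairs_sig = vapply(x$dc, function(d)
      sum(d$q_diff <= x$thresholds$dc_q), 1L),
    dk_genes = vapply(names(x$dc), function(tt)
      if (!is.null(x$dk[[tt]])) sum(x$dk[[tt]]$significant) else NA_integer_,
      1L),
    row.names = NULL
  )
  cat("Per-tissue differential results:\n")
  print(df)
  invisible(df)
}

#' Plot the per-condition connectivity cumulative distributions
#'
#' One panel per tissue showing the cumulative distribution function of node
#' degree in the CON and RES condition-specific networks -- a shift to the
#' right means a gain of connectivity in that condition.
#'
#' @param x `"fetonet"` object.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.fetonet <- function(x, ...) {
  tissues <- names(x$gain)
  if (!length(tissues)) {
    warning("no condition networks to plot")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, length(tissues)))
  on.exit(graphics::par(old))
  for (tt in tissues) {
    cdf <- x$gain[[tt]]$cdf
    plot(NA, xlim = range(cdf$degree), ylim = c(0, 1),
         xlab = "connectivity (degree)", ylab = "cumulative fraction",
         main = tt, ...)
    for (cond in unique(cdf$condition)) {
      d <- cdf[cdf$condition == cond, ]
      graphics::lines(d$degree, d$cum_frac, type = "s",
                      col = ifelse(cond == "CON", "darkgreen", "firebrick"))
    }
    graphics::legend("bottomright", legend = unique(cdf$condition),
                     col = c("darkgreen", "firebrick"), lty = 1, bty = "n")
  }
  invisible(x)
}
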