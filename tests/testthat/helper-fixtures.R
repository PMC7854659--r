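# Shared fixtures, built in code.

# Small default-scale dataset (7 + 7 per tissue), cached per test run.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(sim_config(seed = 101L))
    cache
  }
})

# Study variant with 30 fetuses per condition, plus the derived pipeline
# results used by the planted-structure tests (computed once).
big_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- fetonet(sim = sim_config(n_per_condition = 30, seed = 11L),
                        seed = 11L, verbose = FALSE)
    cache
  }
})

# random symmetric correlation matrix from n_samples Gaussian profiles
random_corr <- function(n_genes, n_samples = 20) {
  x <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  r <- stats::cor(t(x))
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  diag(r) <- 1
  r
}

# tiny network from an explicit edge list
toy_net <- function(edges, genes = NULL) {
  ed <- data.frame(from = pmin(edges[, 1], edges[, 2]),
                   to = pmax(edges[, 1], edges[, 2]),
                   weight = 1, stringsAsFactors = FALSE)
  ed <- ed[order(ed$from, ed$to), ]
  if (is.null(genes)) genes <- sort(unique(c(ed$from, ed$to)))
  deg <- table(factor(c(ed$from, ed$to), levels = genes))
  structure(list(
    nodes = data.frame(gene = genes, degree = as.integer(deg[genes]),
                       stringsAsFactors = FALSE),
    edges = ed, params = list(min_abs_r = NA)
  ), class = "coexnet")
}
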