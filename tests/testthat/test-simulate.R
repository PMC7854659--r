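test_that("simulated dataset has the declared design and is reproducible", {
  ds <- small_sim()
  cfg <- ds$config
  expect_equal(dim(ds$counts),
               c(cfg$n_genes, cfg$n_tissues * 2 * cfg$n_per_condition))
  expect_true(all(ds$counts >= 0))
  expect_true(all(ds$counts == round(ds$counts)))
  expect_setequal(unique(ds$metadata$tissue), cfg$tissue_names)
  expect_equal(as.integer(table(ds$metadata$condition)),
               rep(cfg$n_tissues * cfg$n_per_condition, 2L))
  # same fetus keeps its sex across tissues
  sex_by_fetus <- tapply(ds$metadata$sex, ds$metadata$fetus,
                         function(s) length(unique(s)))
  expect_true(all(sex_by_fetus == 1))
  # determinism
  ds2 <- simulate_dataset(sim_config(seed = 101L))
  expect_identical(ds$counts, ds2$counts)
  expect_identical(ds$truth, ds2$truth)
  # a different seed changes the data
  ds3 <- simulate_dataset(sim_config(seed = 102L))
  expect_false(identical(ds$counts, ds3$counts))
})

test_that("ground truth is consistent with the count matrix", {
  ds <- small_sim()
  tr <- ds$truth
  genes <- rownames(ds$counts)
  expect_true(all(tr$ts_genes$gene %in% genes))
  expect_true(all(tr$de_genes$gene %in% genes))
  expect_true(all(tr$tf_genes %in% genes))
  mods <- tr$modules
  expect_true(all(unlist(lapply(mods, function(m)
    c(m$regulator, m$members))) %in% genes))
  # rewired genes are exactly the members of coupling-changed modules
  expected <- unlist(lapply(mods, function(m)
    if (m$coupling_con != m$coupling_res) c(m$regulator, m$members)))
  expect_setequal(tr$rewired_genes, expected)
  # planted blocks are disjoint
  planted <- c(tr$ts_genes$gene,
               unlist(lapply(mods, function(m) c(m$regulator, m$members))))
  expect_equal(anyDuplicated(planted), 0L)
})

test_that("infeasible gene budgets and bad couplings are rejected", {
  expect_error(sim_config(n_genes = 50, n_ts_per_tissue = 30),
               "gene budget")
  expect_error(sim_config(coupling_con = 1.2), "couplings")
})

test_that("an extreme tissue-specific contrast drives tau to 1 downstream", {
  cfg <- sim_config(n_genes = 100, n_ts_per_tissue = 2, ts_fold = 1e6,
                    n_de = 0, n_modules = 0, seed = 5L)
  ds <- simulate_dataset(cfg)
  norm <- normalize_counts(ds$counts, ds$metadata, "pooled")
  mns <- tissue_means(norm, ds$metadata)
  tau <- tau_table(mns)
  planted <- tau[match(ds$truth$ts_genes$gene, tau$gene), ]
  expect_true(all(planted$tau > 0.99, na.rm = TRUE))
})

test_that("planted module coupling is recovered in the observed correlations", {
  # generative oracle: at large n the within-condition Pearson correlation
  # between the regulator and each member approaches the configured coupling
  cfg <- sim_config(n_genes = 120, n_tissues = 1, tissue_names = "muscle",
                    n_ts_per_tissue = 5, n_de = 10,
                    n_modules = 1, module_size = 10,
                    coupling_con = 0.9, coupling_res = -0.9,
                    n_per_condition = 400, seed = 7L)
  ds <- simulate_dataset(cfg)
  norm <- normalize_counts(ds$counts, ds$metadata, "pooled")
  m <- ds$truth$modules[[1]]
  for (cond in c("CON", "RES")) {
    s <- ds$metadata$sample[ds$metadata$condition == cond]
    r <- stats::cor(t(norm[c(m$regulator, m$members), s]))[1, -1]
    target <- if (cond == "CON") m$coupling_con else m$coupling_res
    expect_true(all(abs(r - target) < 0.1),
                label = sprintf("%s coupling recovery", cond))
  }
})

test_that("per-gene mean CPM tracks the generative mean", {
  cfg <- sim_config(n_genes = 200, n_tissues = 1, tissue_names = "liver",
                    n_ts_per_tissue = 0, n_de = 0, n_modules = 0,
                    n_per_condition = 100, sex_frac = 0, seed = 9L)
  ds <- simulate_dataset(cfg)
  obs <- rowMeans(cpm(ds$counts))
  # background-only config: all genes share the same noise model, so the
  # expected CPM is just the baseline renormalized to a million
  expected <- 1e6 * ds$baseline / sum(ds$baseline)
  expect_lt(median(abs(obs / expected - 1)), 0.1)
})

test_that("truth tables round-trip through TSV", {
  ds <- small_sim()
  d <- withr::local_tempdir()
  write_truth(ds$truth, d, genes = rownames(ds$counts))
  back <- read_truth(d)
  expect_equal(back$ts_genes, ds$truth$ts_genes)
  expect_equal(back$de_genes, ds$truth$de_genes)
  expect_setequal(back$tf_genes, ds$truth$tf_genes)
  expect_setequal(back$rewired_genes, ds$truth$rewired_genes)
  expect_equal(length(back$modules), length(ds$truth$modules))
  m0 <- ds$truth$modules[[1]]; m1 <- back$modules[[1]]
  expect_equal(m1$regulator, m0$regulator)
  expect_setequal(m1$members, m0$members)
  # unknown gene in truth is a validation error
  bad <- ds$truth
  bad$tf_genes <- c(bad$tf_genes, "not_a_gene")
  expect_error(write_truth(bad, d, genes = rownames(ds$counts)),
               "unknown gene")
  # empty module list still writes a valid file
  none <- ds$truth
  none$modules <- list()
  d2 <- withr::local_tempdir()
  write_truth(none, d2, genes = rownames(ds$counts))
  expect_equal(length(read_truth(d2)$modules), 0L)
})
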