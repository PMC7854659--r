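test_that("cpm normalizes columns to one million", {
  m <- matrix(c(500, 999500, 30, 70), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  x <- cpm(m)
  expect_equal(x["g1", "s1"], 500)
  expect_equal(unname(x[, "s2"]), c(300000, 700000))
  expect_equal(unname(colSums(x)), c(1e6, 1e6))
  m[, 1] <- 0
  expect_error(cpm(m), "s1")
})

test_that("low-expression filter uses the >= ceiling(fraction * n) rule", {
  # 14 samples: removal needs >= ceiling(0.8 * 14) = 12 low samples
  n <- 14
  base <- matrix(1000, 3, n,
                 dimnames = list(c("keep11", "drop12", "allzero"),
                                 paste0("s", 1:n)))
  # library ~ 1e6 per sample so CPM ~ count
  filler <- matrix(1e6, 1, n, dimnames = list("filler", paste0("s", 1:n)))
  base["keep11", 1:11] <- 0   # low in 11 samples -> kept
  base["drop12", 1:12] <- 0   # low in 12 samples -> removed
  base["allzero", ] <- 0
  m <- rbind(base, filler)
  out <- filter_low_expression(m)
  expect_setequal(rownames(out), c("keep11", "filler"))
  # gene order preserved
  expect_equal(rownames(out), c("keep11", "filler"))
  expect_error(filter_low_expression(m, fraction = 0), "fraction")
  # idempotence
  expect_identical(filter_low_expression(out), out)
})

test_that("median-of-ratios size factors match the hand toy", {
  a <- c(10, 20, 30, 40, 50)
  m <- cbind(s1 = a, s2 = 2 * a)
  rownames(m) <- paste0("g", 1:5)
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  # identical samples -> all 1
  expect_equal(unname(estimate_size_factors(cbind(a, a, a))), rep(1, 3))
  # single sample -> 1
  expect_equal(unname(estimate_size_factors(cbind(s1 = a))), 1)
  # no common nonzero gene
  bad <- cbind(c(1, 0), c(0, 1))
  expect_error(estimate_size_factors(bad), "filter")
})

test_that("vst transform is log2(x/sf + 1)", {
  m <- matrix(c(0, 7), 1, 2, dimnames = list("g", c("a", "b")))
  v <- vst_transform(m, c(1, 1))
  expect_equal(unname(v[1, ]), c(0, 3))
  # doubling the size factor halves the pre-log value
  v2 <- vst_transform(m, c(1, 2))
  expect_equal(unname(v2[1, 2]), log2(7 / 2 + 1))
  expect_error(vst_transform(m, c(1, -1)), "positive")
})

test_that("dispersion filter removes the lowest-CV quantile", {
  set.seed(1)
  n <- 10
  m <- t(sapply(1:n, function(i) 5 + i * 0.3 * scale(rnorm(8))[, 1]))
  rownames(m) <- paste0("g", 1:n)
  colnames(m) <- paste0("s", 1:8)
  cv <- apply(m, 1, sd) / rowMeans(m)
  expect_equal(length(unique(cv)), n)  # strictly distinct by construction
  out <- filter_low_dispersion(m, 0.2)
  expect_equal(nrow(out), 8)
  expect_setequal(rownames(out), rownames(m)[rank(cv) > 2])
  # constant gene removed when others vary
  m2 <- rbind(m, flat = rep(5, 8))
  expect_false("flat" %in% rownames(filter_low_dispersion(m2, 0.2)))
  # quantile 0 is the identity
  expect_identical(filter_low_dispersion(m, 0), m)
  # fully degenerate matrix warns and removes nothing
  m3 <- matrix(5, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_warning(out3 <- filter_low_dispersion(m3, 0.2), "identical")
  expect_equal(nrow(out3), 5)
})

test_that("covariate adjustment equalizes group means and recovers effects", {
  set.seed(42)
  n <- 42
  meta <- data.frame(sample = paste0("s", 1:n),
                     sex = rep(c("M", "F"), length.out = n))
  base <- matrix(rnorm(20 * n, mean = 6, sd = 0.15), 20, n,
                 dimnames = list(paste0("g", 1:20), meta$sample))
  planted <- 0.5
  m <- base
  m[1:5, meta$sex == "M"] <- m[1:5, meta$sex == "M"] + planted
  # OLS oracle: the fitted sex effect before removal is ~0.5
  est <- sapply(1:5, function(i)
    coef(lm(m[i, ] ~ meta$sex))[2])  # F is reference: effect of M
  expect_true(all(abs(est - planted) < 0.1))
  adj <- adjust_covariate(m, meta, "sex")
  gm_m <- rowMeans(adj[, meta$sex == "M"])
  gm_f <- rowMeans(adj[, meta$sex == "F"])
  expect_true(all(abs(gm_m - gm_f) < 1e-10))
  # grand mean preserved
  expect_equal(rowMeans(adj), rowMeans(m))
  # orthogonal covariate leaves genes ~unchanged up to the small fitted tilt
  expect_lt(max(abs(adj[6:20, ] - m[6:20, ])), 1)
  # single-level covariate is a warning no-op
  meta1 <- transform(meta, sex = "M")
  expect_warning(adj1 <- adjust_covariate(m, meta1, "sex"), "single")
  expect_identical(adj1, m)
})

test_that("both normalization strategies run and declare their gene sets", {
  ds <- small_sim()
  n1 <- normalize_counts(ds$counts, ds$metadata, "pooled")
  expect_true(is.matrix(n1))
  expect_true(all(is.finite(n1)))
  n2 <- normalize_counts(ds$counts, ds$metadata, "per_tissue")
  expect_setequal(names(n2), unique(ds$metadata$tissue))
  for (tt in names(n2)) {
    expect_true(all(rownames(n2[[tt]]) %in% rownames(ds$counts)))
    # per-tissue matrices only contain that tissue's samples
    expect_setequal(colnames(n2[[tt]]),
                    ds$metadata$sample[ds$metadata$tissue == tt])
    # dispersion filter made the per-tissue set smaller
    expect_lt(nrow(n2[[tt]]), nrow(n1))
  }
})
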