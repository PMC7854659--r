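make_cc <- function(con, res, e_con, e_res, tfs = NULL, targets = NULL) {
  if (is.null(tfs)) tfs <- paste0("tf", seq_len(nrow(con)))
  if (is.null(targets)) targets <- paste0("t", seq_len(ncol(con)))
  dimnames(con) <- dimnames(res) <- list(tfs, targets)
  list(con = con, res = res,
       targets = data.frame(
         target = targets, e_con = e_con, e_res = e_res,
         abundance = (e_con + e_res) / 2, de = e_con - e_res,
         pif = (e_con + e_res) / 2 * (e_con - e_res),
         stringsAsFactors = FALSE))
}

test_that("RIF raw scores match the hand-worked single pair", {
  cc <- make_cc(matrix(0.8), matrix(-0.4), e_con = 10, e_res = 6)
  r <- rif_scores(cc)
  # abar = 8, d = 4, dw = 1.2 -> RIF1 = 8*4*1.44; RIF2 = (10*.8)^2-(6*.4)^2
  expect_equal(r$rif1_raw, 46.08)
  expect_equal(r$rif2_raw, 58.24)
})

test_that("identical conditions give zero raw scores; swapping negates them", {
  set.seed(3)
  con <- matrix(stats::runif(12, -1, 1), 3, 4)
  e <- stats::runif(4, 2, 10)
  cc_same <- make_cc(con, con, e, e)
  r <- rif_scores(cc_same)
  expect_equal(r$rif1_raw, rep(0, 3))
  expect_equal(r$rif2_raw, rep(0, 3))

  res <- matrix(stats::runif(12, -1, 1), 3, 4)
  e2 <- stats::runif(4, 2, 10)
  fwd <- rif_scores(make_cc(con, res, e, e2))
  rev <- rif_scores(make_cc(res, con, e2, e))
  expect_equal(rev$rif1_raw, -fwd$rif1_raw)
  expect_equal(rev$rif2_raw, -fwd$rif2_raw)
})

test_that("scaling all expression by c scales both raw scores by c^2", {
  set.seed(4)
  con <- matrix(stats::runif(8, -1, 1), 2, 4)
  res <- matrix(stats::runif(8, -1, 1), 2, 4)
  e1 <- stats::runif(4, 2, 10); e2 <- stats::runif(4, 2, 10)
  base <- rif_scores(make_cc(con, res, e1, e2))
  scaled <- rif_scores(make_cc(con, res, 3 * e1, 3 * e2))
  expect_equal(scaled$rif1_raw, 9 * base$rif1_raw)
  expect_equal(scaled$rif2_raw, 9 * base$rif2_raw)
})

test_that("condition correlations use within-condition samples only", {
  set.seed(5)
  meta <- data.frame(sample = paste0("s", 1:10),
                     condition = rep(c("CON", "RES"), each = 5))
  m <- matrix(stats::rnorm(40), 4, 10,
              dimnames = list(c("tf1", "t1", "t2", "flat"), meta$sample))
  m["t1", ] <- m["tf1", ]  # identical to the TF
  m["flat", ] <- 1
  expect_warning(
    cc <- condition_correlations(m, meta, "tf1", c("t1", "t2", "flat")),
    "zero-variance")
  expect_equal(cc$con["tf1", "t1"], 1)
  expect_equal(cc$res["tf1", "t1"], 1)
  expect_equal(cc$con["tf1", "flat"], 0)
  # hand Pearson on the 5 CON samples
  r_hand <- stats::cor(m["tf1", 1:5], m["t2", 1:5])
  expect_equal(cc$con["tf1", "t2"], r_hand)
  expect_equal(cc$targets$pif,
               cc$targets$abundance * cc$targets$de)
  expect_error(condition_correlations(m, meta, "tf1", "nope"), "absent")
})

test_that("regulator ranking is by max |z| with stable ties", {
  set.seed(6)
  con <- rbind(strong = rep(0.9, 5), matrix(0.01 * stats::rnorm(45), 9, 5))
  res <- rbind(strong = rep(-0.9, 5), matrix(0.01 * stats::rnorm(45), 9, 5))
  rownames(con) <- rownames(res) <- c("strong", paste0("tf", 1:9))
  e <- rep(5, 5)
  r <- rank_regulators(rif_scores(make_cc(con, res, e + 1, e,
                                          tfs = rownames(con))))
  expect_equal(r$tf[1], "strong")
  # input order does not change the ranking
  perm <- sample(nrow(con))
  r2 <- rank_regulators(rif_scores(make_cc(con[perm, ], res[perm, ],
                                           e + 1, e,
                                           tfs = rownames(con)[perm])))
  expect_equal(r2$tf, r$tf)
})

test_that("null RIF calibration: significant fraction stays near nominal", {
  # both conditions drawn from one generative model; z-standardization over
  # a finite, skewed score distribution is approximate, so the empirical
  # rate at p <= 0.01 is bounded at 0.10 rather than matched exactly
  set.seed(7)
  n_tf <- 200; n_tgt <- 20; n <- 10
  reps <- 500
  frac <- numeric(reps)
  meta <- data.frame(sample = paste0("s", 1:(2 * n)),
                     condition = rep(c("CON", "RES"), each = n))
  for (b in seq_len(reps)) {
    m <- matrix(stats::rnorm((n_tf + n_tgt) * 2 * n, mean = 5),
                n_tf + n_tgt, 2 * n,
                dimnames = list(c(paste0("tf", 1:n_tf),
                                  paste0("t", 1:n_tgt)),
                                meta$sample))
    cc <- condition_correlations(m, meta, paste0("tf", 1:n_tf),
                                 paste0("t", 1:n_tgt))
    r <- rif_scores(cc, alpha = 0.01)
    frac[b] <- mean(r$significant)
  }
  expect_lte(mean(frac), 0.10)
})
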