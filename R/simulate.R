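#' Configuration for the synthetic multi-tissue two-condition dataset
#'
#' Builds and validates the parameter list consumed by [simulate_dataset()].
#' The defaults emulate a fetal programming study design: three tissues
#' (cerebrum, liver, muscle) sampled from the same fetuses, two maternal-diet
#' conditions (control `CON` and nutrient-restricted `RES`) with seven fetuses
#' each, plus planted structure for every downstream analysis -- tissue-specific
#' genes for the Tau index, differentially expressed genes, and TF-regulated
#' modules whose regulator--target correlation differs between conditions (the
#' signal for RIF, differential co-expression and differential connectivity).
#'
#' Counts follow a Gamma-Poisson (negative binomial) model around a log-scale
#' mean: baseline + tissue-specific elevation (home tissue only) + differential
#' expression shift (RES only) + module loading x a per-sample latent factor,
#' scaled by a per-sample library size. Module correlation is induced by one
#' standard-Gaussian latent factor per module and sample; the module regulator
#' carries the factor with loading 1 and target loadings are calibrated so the
#' observed log-scale regulator--target correlation (accounting for biological
#' and counting noise via the delta method) matches the configured coupling.
#'
#' @param n_genes total number of genes.
#' @param n_tissues number of tissues (length of `tissue_names`).
#' @param n_per_condition fetuses per condition; each fetus contributes one
#'   sample per tissue.
#' @param tissue_names,condition_names labels; `condition_names[1]` is the
#'   reference (control) condition.
#' @param n_ts_per_tissue planted tissue-specific genes per tissue.
#' @param ts_fold fold elevation (count scale) of a TS gene in its home tissue
#'   relative to the other tissues; must be > 1.
#' @param n_de planted differentially expressed background genes.
#' @param de_log2fc log2 fold change (RES vs CON) of planted DE genes and of
#'   module member genes.
#' @param n_modules,module_size number of TF--target modules and genes per
#'   module (the first gene of each module is its regulator).
#' @param coupling_con,coupling_res per-module target correlation between the
#'   regulator and each member gene, within each condition; vectors of length
#'   `n_modules` (recycled), each in (-1, 1).
#' @param n_tf_background background genes added to the TF catalogue so that
#'   RIF z-scores are standardized over a realistic number of TFs.
#' @param nb_dispersion negative binomial dispersion (Var = mu + phi mu^2).
#' @param library_size_mean,library_size_cv mean and coefficient of variation
#'   of the per-sample sequencing depth.
#' @param bio_noise_sd per-gene biological noise standard deviation on the
#'   natural-log scale.
#' @param sex_effect,sex_frac additive log2 effect of fetal sex applied to a
#'   random fraction of background genes (exercises covariate adjustment).
#' @param ts_mean,module_mean expected home-tissue / module-gene count at the
#'   nominal library size.
#' @param seed integer seed; the whole dataset is reproducible from it.
#'
#' @return a validated list of class `"sim_config"`.
#' @seealso [simulate_dataset()]
#' @export
sim_config <- function(n_genes = 600,
                       n_tissues = 3,
                       n_per_condition = 7,
                       tissue_names = c("cerebrum", "liver", "muscle"),
                       condition_names = c("CON", "RES"),
                       n_ts_per_tissue = 30,
                       ts_fold = 300,
                       n_de = 40,
                       de_log2fc = 1,
                       n_modules = 3,
                       module_size = 20,
                       coupling_con = c(0.8, 0.95, 0.95),
                       coupling_res = c(-0.8, 0.0, 0.95),
                       n_tf_background = 57,
                       nb_dispersion = 0.05,
                       library_size_mean = 1e6,
                       library_size_cv = 0.2,
                       bio_noise_sd = 0.3,
                       sex_effect = 0.5,
                       sex_frac = 0.01,
                       ts_mean = 300,
                       module_mean = 1500,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
    n_per_condition = as.integer(n_per_condition),
    tissue_names = as.character(tissue_names),
    condition_names = as.character(condition_names),
    n_ts_per_tissue = as.integer(n_ts_per_tissue), ts_fold = ts_fold,
    n_de = as.integer(n_de), de_log2fc = de_log2fc,
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    coupling_con = rep_len(coupling_con, n_modules),
    coupling_res = rep_len(coupling_res, n_modules),
    n_tf_background = as.integer(n_tf_background),
    nb_dispersion = nb_dispersion,
    library_size_mean = library_size_mean, library_size_cv = library_size_cv,
    bio_noise_sd = bio_noise_sd,
    sex_effect = sex_effect, sex_frac = sex_frac,
    ts_mean = ts_mean, module_mean = module_mean,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_genes >= 1, cfg$n_tissues >= 1, cfg$n_per_condition >= 1,
    length(cfg$tissue_names) == cfg$n_tissues,
    length(cfg$condition_names) == 2,
    cfg$ts_fold > 1, cfg$nb_dispersion > 0,
    cfg$library_size_mean > 0, cfg$library_size_cv >= 0,
    cfg$n_ts_per_tissue >= 0, cfg$n_de >= 0, cfg$n_modules >= 0,
    cfg$n_modules == 0 || cfg$module_size >= 2
  )
  if (any(abs(cfg$coupling_con) >= 1) || any(abs(cfg$coupling_res) >= 1))
    stop("module couplings must lie strictly within (-1, 1)")
  planted <- cfg$n_ts_per_tissue * cfg$n_tissues +
    cfg$n_modules * cfg$module_size + cfg$n_de
  if (planted > cfg$n_genes)
    stop(sprintf(
      "infeasible gene budget: %d planted genes exceed n_genes = %d",
      planted, cfg$n_genes
    ))
  invisible(cfg)
}

# Target loading for observed-scale correlation rho between the regulator
# (loading 1, no biological noise) and a member gene, accounting for
# measurement noise var v ~ 1/mu + phi on the log scale (delta method) and
# biological noise s2 on the member.
.module_loading <- function(rho, s2, v_reg, v_tgt) {
  if (rho == 0) return(0)
  k <- rho^2 * (1 + v_reg)
  if (k >= 1) stop("coupling too strong for the configured noise level")
  sign(rho) * sqrt(k * (s2 + v_tgt) / (1 - k))
}

#' Simulate a multi-tissue two-condition RNA-seq count dataset
#'
#' Draws a genes x samples negative-binomial count matrix with planted
#' tissue-specific genes, differentially expressed genes and condition-rewired
#' TF--target modules, together with sample metadata and the ground-truth
#' tables needed to score recovery. See [sim_config()] for the generative
#' model.
#'
#' @param config a [sim_config()] object (or a list accepted by it).
#' @return a list of class `"fetosim"` with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples.}
#'     \item{metadata}{data.frame with `sample`, `tissue`, `condition`,
#'       `sex`, `fetus`.}
#'     \item{truth}{ground truth list: `ts_genes` (gene, tissue),
#'       `de_genes` (gene, log2fc), `modules` (per-module regulator, members
#'       and couplings), `rewired_genes`, `tf_genes`.}
#'     \item{baseline}{per-gene expected count at the nominal library size,
#'       before tissue/condition/module effects (the generative mean).}
#'   }
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)
  cfg <- config

  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  idx <- seq_len(cfg$n_genes)

  # planted gene allocation (disjoint blocks, remainder is background)
  n_ts_tot <- cfg$n_ts_per_tissue * cfg$n_tissues
  ts_idx <- if (n_ts_tot > 0) idx[seq_len(n_ts_tot)] else integer(0)
  ts_home <- rep(cfg$tissue_names, each = cfg$n_ts_per_tissue)
  mod_idx <- if (cfg$n_modules > 0)
    idx[n_ts_tot + seq_len(cfg$n_modules * cfg$module_size)] else integer(0)
  de_idx <- if (cfg$n_de > 0)
    idx[n_ts_tot + length(mod_idx) + seq_len(cfg$n_de)] else integer(0)
  bg_idx <- setdiff(idx, c(ts_idx, mod_idx, de_idx))

  modules <- vector("list", cfg$n_modules)
  for (m in seq_len(cfg$n_modules)) {
    block <- mod_idx[(m - 1L) * cfg$module_size + seq_len(cfg$module_size)]
    modules[[m]] <- list(
      module = paste0("M", m),
      regulator = genes[block[1]],
      members = genes[block[-1]],
      coupling_con = cfg$coupling_con[m],
      coupling_res = cfg$coupling_res[m]
    )
  }

  # samples: each fetus (condition x replicate) contributes one sample/tissue
  meta <- expand.grid(
    rep = seq_len(cfg$n_per_condition),
    condition = cfg$condition_names,
    tissue = cfg$tissue_names,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  meta$fetus <- paste0(meta$condition, meta$rep)
  meta$sex <- ifelse(meta$rep %% 2 == 1, "M", "F")
  meta$sample <- paste(meta$tissue, meta$condition, meta$rep, sep = "_")
  meta <- meta[, c("sample", "tissue", "condition", "sex", "fetus")]
  n_s <- nrow(meta)

  # baseline expected counts at nominal depth
  mu0 <- numeric(cfg$n_genes)
  mu0[bg_idx] <- 2^stats::runif(length(bg_idx), log2(50), log2(5000))
  mu0[de_idx] <- 2^stats::runif(length(de_idx), log2(100), log2(2000))
  mu0[ts_idx] <- cfg$ts_mean
  mu0[mod_idx] <- cfg$module_mean

  # log-scale (natural log) mean matrix
  eta <- matrix(log(mu0), cfg$n_genes, n_s)
  # TS: home-tissue elevation is relative -- off-tissue mean = ts_mean/ts_fold
  if (length(ts_idx)) {
    off <- log(cfg$ts_fold)
    for (j in seq_len(n_s)) {
      away <- ts_home != meta$tissue[j]
      eta[ts_idx[away], j] <- eta[ts_idx[away], j] - off
    }
  }
  # DE shift (RES only) on planted DE genes and module members
  res_cols <- meta$condition == cfg$condition_names[2]
  de_shift_idx <- c(de_idx, mod_idx)
  if (length(de_shift_idx) && any(res_cols))
    eta[de_shift_idx, res_cols] <- eta[de_shift_idx, res_cols] +
      cfg$de_log2fc * log(2)

  # sex effect on a random subset of background genes
  sex_idx <- integer(0)
  n_sex <- round(cfg$sex_frac * cfg$n_genes)
  if (n_sex > 0 && length(bg_idx) >= n_sex) {
    sex_idx <- sample(bg_idx, n_sex)
    male <- meta$sex == "M"
    eta[sex_idx, male] <- eta[sex_idx, male] + cfg$sex_effect * log(2)
  }

  # module latent factors
  s2 <- cfg$bio_noise_sd^2
  v_reg <- 1 / cfg$module_mean + cfg$nb_dispersion
  for (m in seq_len(cfg$n_modules)) {
    block <- mod_idx[(m - 1L) * cfg$module_size + seq_len(cfg$module_size)]
    f <- stats::rnorm(n_s)
    rho <- ifelse(res_cols, cfg$coupling_res[m], cfg$coupling_con[m])
    lam <- vapply(unique(rho), function(r)
      .module_loading(r, s2, v_reg, v_reg), numeric(1))
    names(lam) <- as.character(unique(rho))
    load_s <- lam[as.character(rho)]
    # regulator: loading 1, no extra biological noise
    eta[block[1], ] <- eta[block[1], ] + f
    # members: calibrated loading + biological noise
    mem <- block[-1]
    eta[mem, ] <- eta[mem, ] +
      outer(rep(1, length(mem)), load_s * f) +
      matrix(stats::rnorm(length(mem) * n_s, sd = cfg$bio_noise_sd),
             length(mem), n_s)
  }
  # biological noise for all non-module genes
  nonmod <- setdiff(idx, mod_idx)
  eta[nonmod, ] <- eta[nonmod, ] +
    matrix(stats::rnorm(length(nonmod) * n_s, sd = cfg$bio_noise_sd),
           length(nonmod), n_s)

  # per-sample depth and NB sampling
  sdlog <- sqrt(log(1 + cfg$library_size_cv^2))
  depth <- stats::rlnorm(n_s, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  mu <- exp(eta) * rep(depth, each = cfg$n_genes)
  counts <- matrix(
    stats::rnbinom(length(mu), size = 1 / cfg$nb_dispersion, mu = mu),
    cfg$n_genes, n_s, dimnames = list(genes, meta$sample)
  )
  storage.mode(counts) <- "integer"

  tf_genes <- character(0)
  if (cfg$n_modules > 0)
    tf_genes <- vapply(modules, `[[`, character(1), "regulator")
  if (cfg$n_tf_background > 0) {
    pool <- genes[setdiff(bg_idx, sex_idx)]
    tf_genes <- c(tf_genes,
                  sample(pool, min(cfg$n_tf_background, length(pool))))
  }

  rewired <- unlist(lapply(modules, function(m) {
    if (m$coupling_con != m$coupling_res) c(m$regulator, m$members)
    else character(0)
  }))

  truth <- list(
    ts_genes = data.frame(gene = genes[ts_idx], tissue = ts_home,
                          stringsAsFactors = FALSE),
    de_genes = data.frame(
      gene = genes[c(de_idx, mod_idx)],
      log2fc = rep(cfg$de_log2fc, length(de_idx) + length(mod_idx)),
      stringsAsFactors = FALSE
    ),
    modules = modules,
    rewired_genes = rewired,
    tf_genes = tf_genes,
    sex_genes = genes[sex_idx]
  )

  structure(list(counts = counts, metadata = meta, truth = truth,
                 baseline = stats::setNames(mu0, genes), config = cfg),
            class = "fetosim")
}

#' @export
print.fetosim <- function(x, ...) {
  cat("Synthetic multi-tissue RNA-seq dataset\n")
  cat(sprintf("  %d genes x %d samples (%d tissues x 2 conditions x %d)\n",
              nrow(x$counts), ncol(x$counts), x$config$n_tissues,
              x$config$n_per_condition))
  cat(sprintf("  planted: %d TS genes, %d DE genes, %d modules, %d TFs\n",
              nrow(x$truth$ts_genes), nrow(x$truth$de_genes),
              length(x$truth$modules), length(x$truth$tf_genes)))
  invisible(x)
}

#' Write ground-truth tables to TSV files
#'
#' Serializes a `truth` list (as produced by [simulate_dataset()]) into
#' plain TSV files (`truth_ts.tsv`, `truth_de.tsv`, `truth_modules.tsv`,
#' `truth_tf.tsv`) that round-trip losslessly through [read_truth()].
#'
#' @param truth ground truth list.
#' @param dir output directory (created if missing).
#' @param genes optional character vector of valid gene ids; if supplied,
#'   any truth gene absent from it raises an error.
#' @return invisibly, the vector of files written.
#' @export
write_truth <- function(truth, dir, genes = NULL) {
  if (!is.null(genes)) {
    all_genes <- unique(c(
      truth$ts_genes$gene, truth$de_genes$gene, truth$tf_genes,
      unlist(lapply(truth$modules, function(m) c(m$regulator, m$members)))
    ))
    bad <- setdiff(all_genes, genes)
    if (length(bad))
      stop("truth references unknown genes: ", paste(bad, collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE
  )
  wt(truth$ts_genes, "truth_ts.tsv")
  wt(truth$de_genes, "truth_de.tsv")
  mod_df <- do.call(rbind, lapply(truth$modules, function(m) data.frame(
    module = m$module,
    gene = c(m$regulator, m$members),
    role = c("regulator", rep("member", length(m$members))),
    coupling_con = m$coupling_con, coupling_res = m$coupling_res,
    stringsAsFactors = FALSE
  )))
  if (is.null(mod_df))
    mod_df <- data.frame(module = character(0), gene = character(0),
                         role = character(0), coupling_con = numeric(0),
                         coupling_res = numeric(0))
  wt(mod_df, "truth_modules.tsv")
  wt(data.frame(gene = truth$tf_genes), "truth_tf.tsv")
  invisible(file.path(dir, c("truth_ts.tsv", "truth_de.tsv",
                             "truth_modules.tsv", "truth_tf.tsv")))
}

#' Read ground-truth tables written by [write_truth()]
#'
#' @param dir directory containing the `truth_*.tsv` files.
#' @return a truth list with the same structure as produced by
#'   [simulate_dataset()] (`rewired_genes` is reconstructed from the module
#'   couplings).
#' @export
read_truth <- function(dir) {
  rt <- function(f) utils::read.table(
    file.path(dir, f), sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, colClasses = NA
  )
  ts <- rt("truth_ts.tsv")
  de <- rt("truth_de.tsv")
  mod_df <- rt("truth_modules.tsv")
  tf <- rt("truth_tf.tsv")
  modules <- lapply(split(mod_df, mod_df$module), function(d) list(
    module = d$module[1],
    regulator = d$gene[d$role == "regulator"],
    members = d$gene[d$role == "member"],
    coupling_con = d$coupling_con[1],
    coupling_res = d$coupling_res[1]
  ))
  modules <- unname(modules[order(names(modules))])
  rewired <- unlist(lapply(modules, function(m) {
    if (m$coupling_con != m$coupling_res) c(m$regulator, m$members)
    else character(0)
  }))
  list(ts_genes = ts, de_genes = de, modules = modules,
       rewired_genes = if (is.null(rewired)) character(0) else rewired,
       tf_genes = tf$gene)
}
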