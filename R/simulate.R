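#' Configuration of the genotype/phenotype simulator
#'
#' Describes the generative design used throughout the package's
#' validation studies: `N = 253` samples genotyped at `P = 1000`
#' independent biallelic SNPs, a `Q = 100`-dimensional multivariate-normal
#' phenotype, and additive genetic effects from 5 causal SNPs of minor
#' allele frequency at least 0.2, calibrated so that the genetic component
#' explains about 8% of the phenotypic variance of the affected traits.
#' Non-causal minor allele frequencies are uniform on `maf_range`
#' (defaulting to 0.1–0.5, the post-QC range).  The noise covariance is
#' exchangeable with correlation `rho = 0.3` by default — traits standing
#' in for voxel-wise measures are correlated — with identity and
#' user-supplied alternatives.  Each causal SNP affects a random
#' `effect_sparsity` share of traits with equal magnitude and random sign.
#'
#' @param n_samples,n_snps,n_traits problem dimensions.
#' @param maf_range range of non-causal minor allele frequencies.
#' @param n_causal number of causal SNPs.
#' @param causal_maf minimum minor allele frequency of causal SNPs.
#' @param target_var_explained genetic share of phenotypic variance on the
#'   affected traits (in `(0, 1)`).
#' @param covariance `"exchangeable"`, `"identity"`, or a `Q x Q` matrix.
#' @param rho exchangeable correlation.
#' @param effect_sparsity share of traits each causal SNP affects.
#' @param ld_rho adjacent-SNP haplotype correlation (0 = independent SNPs;
#'   positive values copy a decaying latent haplotype signal across
#'   neighbours).
#' @param master_seed RNG seed for [simulate_dataset()].
#' @return An object of class `mvrf_sim_config`.
#' @export
simulation_config <- function(n_samples = 253, n_snps = 1000, n_traits = 100,
                              maf_range = c(0.1, 0.5), n_causal = 5,
                              causal_maf = 0.2, target_var_explained = 0.08,
                              covariance = "exchangeable", rho = 0.3,
                              effect_sparsity = 0.2, ld_rho = 0,
                              master_seed = 1L) {
  stopifnot(target_var_explained >= 0, target_var_explained < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            effect_sparsity > 0, effect_sparsity <= 1)
  structure(
    list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
         n_traits = as.integer(n_traits), maf_range = maf_range,
         n_causal = as.integer(n_causal), causal_maf = causal_maf,
         target_var_explained = target_var_explained,
         covariance = covariance, rho = rho,
         effect_sparsity = effect_sparsity, ld_rho = ld_rho,
         master_seed = as.integer(master_seed)),
    class = "mvrf_sim_config"
  )
}

#' Simulate an additive-coded genotype matrix
#'
#' Draws each SNP's minor allele frequency uniformly from
#' `config$maf_range` and genotypes as `Binomial(2, MAF)` across samples.
#' With `ld_rho > 0`, alleles are thresholded from two per-sample latent
#' haplotype signals with first-order autoregressive correlation across
#' adjacent SNPs, giving decaying linkage disequilibrium.  Uses R's RNG;
#' seed with `set.seed()` (or use [simulate_dataset()]).
#'
#' @param config an [simulation_config()] object.
#' @return Integer genotype matrix with attribute `maf` (generating
#'   frequencies).
#' @export
simulate_genotypes <- function(config) {
  n <- config$n_samples; p <- config$n_snps
  maf <- runif(p, config$maf_range[1], config$maf_range[2])
  if (config$ld_rho > 0) {
    g <- matrix(0L, n, p)
    for (h in 1:2) {
      lat <- matrix(0, n, p)
      lat[, 1] <- rnorm(n)
      a <- config$ld_rho
      for (j in 2:p) lat[, j] <- a * lat[, j - 1] + sqrt(1 - a^2) * rnorm(n)
      g <- g + (lat < matrix(stats::qnorm(maf), n, p, byrow = TRUE))
    }
    storage.mode(g) <- "integer"
  } else {
    g <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  }
  rownames(g) <- paste0("sample_", seq_len(n))
  colnames(g) <- paste0("snp_", seq_len(p))
  attr(g, "maf") <- maf
  g
}

#' Calibrate the additive effect size to a variance-explained target
#'
#' Scales the effect matrix by a scalar `m` so that the genetic share of
#' phenotypic variance, `Var(m * g_q) / (Var(m * g_q) + V_qq)` averaged
#' over the traits with non-zero effects, equals the target.  `Var(g_q)`
#' is the realized variance of the genetic component on the supplied
#' genotypes (for independent SNPs this is the additive-model variance
#' `sum_c beta_cq^2 * 2 MAF_c (1 - MAF_c)`); the scalar is found by a
#' monotone root search.
#'
#' @param genotypes genotype matrix.
#' @param causal integer indices of the causal SNP columns.
#' @param effects `n_causal x Q` unscaled effect matrix.
#' @param noise_var per-trait noise variances (diagonal of `V`).
#' @param target target variance share in `[0, 1)`.
#' @return Scalar multiplier for the effect matrix.
#' @export
calibrate_effect_size <- function(genotypes, causal, effects, noise_var,
                                  target) {
  stopifnot(target >= 0, target < 1)
  if (target == 0) return(0)
  g_comp <- genotypes[, causal, drop = FALSE] %*% effects
  affected <- which(colSums(effects != 0) > 0)
  g_var <- apply(g_comp[, affected, drop = FALSE], 2, var)
  if (all(g_var <= 0)) stop("degenerate genotypic variance at the causal SNPs")
  s2 <- rep_len(noise_var, ncol(effects))[affected]
  f <- function(m) mean(m^2 * g_var / (m^2 * g_var + s2)) - target
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(0, hi), tol = 1e-12)$root
}

sim_noise <- function(n, q, config) {
  if (is.matrix(config$covariance)) {
    l <- chol(config$covariance)
    matrix(rnorm(n * q), n, q) %*% l
  } else if (identical(config$covariance, "identity")) {
    matrix(rnorm(n * q), n, q)
  } else if (identical(config$covariance, "exchangeable")) {
    rho <- config$rho
    shared <- rnorm(n)
    sqrt(1 - rho) * matrix(rnorm(n * q), n, q) + sqrt(rho) * shared
  } else {
    stop("unknown covariance spec")
  }
}

#' Simulate multivariate phenotypes with additive genetic effects
#'
#' `y_i = m * sum_c x_ic * beta_c + eps_i`, with `eps_i` multivariate
#' normal under the configured covariance and the causal SNPs drawn among
#' those whose empirical minor allele frequency reaches
#' `config$causal_maf`.  Each causal effect vector `beta_c` is supported
#' on a random `effect_sparsity` share of traits with equal magnitude and
#' random sign; `m` comes from [calibrate_effect_size()].  Uses R's RNG.
#'
#' @param genotypes genotype matrix.
#' @param config an [simulation_config()] object.
#' @return List with `phenotypes` (matrix), `causal` (tibble: snp_id,
#'   column, maf), `effects` (scaled effect matrix), `multiplier`.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  n <- nrow(genotypes); q <- config$n_traits
  f <- colMeans(genotypes) / 2
  maf <- pmin(f, 1 - f)
  eligible <- which(maf >= config$causal_maf - 1e-12)
  if (length(eligible) < config$n_causal) {
    stop("too few SNPs reach the causal minor allele frequency")
  }
  causal <- sort(sample(eligible, config$n_causal))
  k <- max(1L, round(config$effect_sparsity * q))
  effects <- matrix(0, config$n_causal, q)
  for (c in seq_len(config$n_causal)) {
    sup <- sample.int(q, k)
    effects[c, sup] <- sample(c(-1, 1), k, replace = TRUE)
  }
  noise_var <- if (is.matrix(config$covariance)) diag(config$covariance) else 1
  m <- calibrate_effect_size(genotypes, causal, effects, noise_var,
                             config$target_var_explained)
  eps <- sim_noise(n, q, config)
  y <- genotypes[, causal, drop = FALSE] %*% (m * effects) + eps
  rownames(y) <- rownames(genotypes)
  colnames(y) <- paste0("trait_", seq_len(q))
  list(
    phenotypes = y,
    causal = tibble::tibble(snp_id = colnames(genotypes)[causal],
                            column = causal, maf = maf[causal]),
    effects = m * effects,
    multiplier = m
  )
}

#' Simulate a complete, reproducible study data set
#'
#' Seeds R's RNG from `config$master_seed`, draws genotypes and
#' phenotypes, and bundles them (with synthetic SNP positions, 5 kb apart
#' on one chromosome, so gene mapping can be exercised) into an
#' [mvrf_data] plus the generating truth.
#'
#' @param config an [simulation_config()] object.
#' @return List with `data` (an `mvrf_data`) and `truth` (causal set,
#'   scaled effects, multiplier).
#' @export
simulate_dataset <- function(config) {
  set.seed(config$master_seed)
  g <- simulate_genotypes(config)
  ph <- simulate_phenotypes(g, config)
  snp_info <- tibble::tibble(
    snp_id = colnames(g), chrom = "1",
    pos = 5000L * seq_len(ncol(g))
  )
  list(
    data = mvrf_data(g, ph$phenotypes, snp_info),
    truth = ph[c("causal", "effects", "multiplier")]
  )
}

#' Monte Carlo comparison of two forest configurations
#'
#' Simulates `n_datasets` independent data sets, fits both forest
#' configurations to each (with tree-growing RNG streams that are
#' independent between the two unless `independent_tree_seeds = FALSE`),
#' and reports the paired OOB errors together with their Pearson
#' correlation across data sets — the design used to compare the standard
#' and distance-based splitting criteria.
#'
#' @param n_datasets number of simulated data sets (at least 2).
#' @param sim_config an [simulation_config()]; its `master_seed` is
#'   re-derived per data set from `seed`.
#' @param config_a,config_b two [mvrf_config()] objects (master seeds are
#'   re-derived per data set).
#' @param seed base seed for the study.
#' @param independent_tree_seeds grow the two forests from independent
#'   per-tree streams (`TRUE`, the comparison design) or identical ones.
#' @return List with `results` (tibble: dataset, oob_a, oob_b) and
#'   `correlation`.
#' @export
simulation_study <- function(n_datasets, sim_config = simulation_config(),
                             config_a = mvrf_config(criterion = "standard"),
                             config_b = mvrf_config(criterion = "distance"),
                             seed = 1L, independent_tree_seeds = TRUE) {
  if (n_datasets < 2) stop("correlation needs at least 2 data sets")
  rows <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    data_seed <- seed + 7919L * i
    sim_config$master_seed <- data_seed
    ds <- simulate_dataset(sim_config)
    config_a$master_seed <- data_seed + 500009L
    config_b$master_seed <- if (independent_tree_seeds) {
      data_seed + 900007L
    } else {
      config_a$master_seed
    }
    fa <- run_forest(ds$data, config_a)
    fb <- run_forest(ds$data, config_b)
    rows[[i]] <- tibble::tibble(dataset = i, oob_a = fa$oob_error,
                                oob_b = fb$oob_error)
  }
  results <- dplyr::bind_rows(rows)
  list(results = results, correlation = cor(results$oob_a, results$oob_b))
}
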