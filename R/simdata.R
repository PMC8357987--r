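#' Configuration for the synthetic twin-cohort generator
#'
#' Defines the study conditions the simulator emulates: twin-pair counts and
#' zygosity mix, omics dimensions, the correlated-CpG block structure, and
#' the trait architecture as variance fractions attributable to a true
#' polygenic component, a true methylation component, and measured
#' covariates. Binary traits are generated under a liability-threshold model
#' with the given prevalence.
#'
#' @param n_pairs number of twin pairs (cohort size is `2 * n_pairs`).
#' @param mz_fraction proportion of monozygotic pairs, in (0, 1].
#' @param n_cpgs,n_snps number of CpGs / SNPs simulated.
#' @param n_causal_cpgs,n_causal_snps causal marker counts (<= totals).
#' @param block_size CpGs per correlated block (final block may be short).
#' @param block_rho within-block latent correlation, in \[0, 1).
#' @param r2_ms_true,r2_pgs_true,r2_cov_true trait variance fractions from
#'   the methylation component, the polygenic component, and covariates;
#'   their sum must be < 1.
#' @param prevalence case fraction for the binary trait, in (0, 1).
#' @param env_rho fraction of the residual trait variance shared within a
#'   pair (common environment); default 0.
#' @param n_discovery effective discovery-cohort size scaling
#'   summary-statistic noise (SE = 1/sqrt(n_discovery)); may be `Inf`.
#' @param seed integer RNG seed; the full output is reproducible from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 500, mz_fraction = 0.5,
                       n_cpgs = 200, n_snps = 200,
                       n_causal_cpgs = 20, n_causal_snps = 20,
                       block_size = 10, block_rho = 0.3,
                       r2_ms_true = 0.10, r2_pgs_true = 0.10,
                       r2_cov_true = 0.05,
                       prevalence = 0.2, env_rho = 0,
                       n_discovery = 1e4, seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs), mz_fraction = mz_fraction,
              n_cpgs = as.integer(n_cpgs), n_snps = as.integer(n_snps),
              n_causal_cpgs = as.integer(n_causal_cpgs),
              n_causal_snps = as.integer(n_causal_snps),
              block_size = as.integer(block_size), block_rho = block_rho,
              r2_ms_true = r2_ms_true, r2_pgs_true = r2_pgs_true,
              r2_cov_true = r2_cov_true, prevalence = prevalence,
              env_rho = env_rho, n_discovery = n_discovery,
              seed = as.integer(seed))
  bad <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  if (cfg$n_pairs < 1) bad("n_pairs must be >= 1")
  if (cfg$mz_fraction <= 0 || cfg$mz_fraction > 1)
    bad("mz_fraction must be in (0, 1]")
  if (cfg$n_causal_cpgs > cfg$n_cpgs) bad("n_causal_cpgs exceeds n_cpgs")
  if (cfg$n_causal_snps > cfg$n_snps) bad("n_causal_snps exceeds n_snps")
  if (cfg$block_size < 1) bad("block_size must be >= 1")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1) bad("block_rho must be in [0, 1)")
  for (f in c("r2_ms_true", "r2_pgs_true", "r2_cov_true")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) bad(paste(f, "must be in [0, 1)"))
  }
  if (cfg$r2_ms_true + cfg$r2_pgs_true + cfg$r2_cov_true >= 1)
    bad("r2_ms_true + r2_pgs_true + r2_cov_true must be < 1")
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1)
    bad("prevalence must be in (0, 1)")
  if (cfg$env_rho < 0 || cfg$env_rho >= 1) bad("env_rho must be in [0, 1)")
  if (cfg$n_discovery <= 0) bad("n_discovery must be positive")
  structure(cfg, class = "sim_config")
}

# scale a raw component to exact sample variance v (zero vector when v = 0);
# returns the scaled component plus the multiplier applied to raw weights
.scale_component <- function(raw, v) {
  if (v == 0 || stats::sd(raw) == 0) {
    return(list(x = numeric(length(raw)), mult = 0))
  }
  mult <- sqrt(v) / stats::sd(raw)
  list(x = (raw - mean(raw)) * mult, mult = mult)
}

#' Simulate a twin cohort with methylation, genotypes and traits
#'
#' Generates a cohort of `2 * n_pairs` individuals. Genotypes follow a
#' per-SNP parental-transmission model: two parents are simulated per
#' family and each twin receives one transmitted allele per parent, so MZ
#' co-twins (a single meiosis, duplicated) have identical dosage rows and
#' DZ co-twins share on average half their alleles. CpG methylation is
#' generated on a latent Gaussian scale with within-block correlation
#' `block_rho` and a linear cell-proportion confounder, then mapped to
#' \[0, 1\] through a logistic squashing around per-CpG baselines. The
#' continuous trait is a weighted sum of causal SNP dosages, causal CpG
#' latent values and covariates plus Gaussian noise, with each component
#' rescaled to its configured variance fraction; the binary trait
#' thresholds an analogous liability at `qnorm(1 - prevalence)`.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_cohort`:
#'   \describe{
#'     \item{beta}{[omics_matrix()] of methylation beta values.}
#'     \item{dosage}{[omics_matrix()] of ALT-allele dosages.}
#'     \item{pheno}{data.frame: sample_id, family_id, zygosity, sex, age,
#'       age_at_trait, cell_prop, batch, PC1, PC2, trait_cont, trait_bin.}
#'     \item{alleles}{data.frame of counted (ALT) and other (REF) alleles
#'       per SNP, for polygenic-score alignment.}
#'     \item{truth}{ground truth: causal ids, true per-marker effects on the
#'       trait scale, latent CpG values, liabilities, realized variance
#'       fractions, SNP allele frequencies.}
#'   }
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  np <- config$n_pairs
  n <- 2L * np
  n_mz <- round(config$mz_fraction * np)

  sample_id <- sprintf("S%05d", seq_len(n))
  family_id <- sprintf("F%04d", rep(seq_len(np), each = 2))
  zygosity <- rep(c("MZ", "DZ")[(rep(seq_len(np), each = 2) > n_mz) + 1L],
                  length.out = n)

  ## --- genotypes: parental transmission per SNP ---------------------------
  snp_ids <- sprintf("rs%06d", seq_len(config$n_snps))
  freq <- stats::runif(config$n_snps, 0.10, 0.90)  # ALT-allele frequency
  allele_pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G"),
                         ncol = 2, byrow = TRUE)  # non-palindromic pairs
  pair_idx <- sample.int(4, config$n_snps, replace = TRUE)
  alleles <- data.frame(snp_id = snp_ids,
                        counted_allele = allele_pairs[pair_idx, 1],
                        other_allele   = allele_pairs[pair_idx, 2],
                        stringsAsFactors = FALSE)

  hap <- function() {
    matrix(stats::rbinom(np * config$n_snps, 1,
                         rep(freq, each = np)), nrow = np)
  }
  M1 <- hap(); M2 <- hap(); F1 <- hap(); F2 <- hap()
  meiosis <- function() {
    sm <- matrix(stats::rbinom(np * config$n_snps, 1, 0.5), nrow = np)
    sf <- matrix(stats::rbinom(np * config$n_snps, 1, 0.5), nrow = np)
    (sm * M1 + (1 - sm) * M2) + (sf * F1 + (1 - sf) * F2)
  }
  twin1 <- meiosis()
  twin2 <- meiosis()
  is_mz_pair <- seq_len(np) <= n_mz
  twin2[is_mz_pair, ] <- twin1[is_mz_pair, ]  # MZ: duplicate the meiosis
  dosage <- matrix(0, nrow = n, ncol = config$n_snps)
  dosage[seq(1, n, 2), ] <- twin1
  dosage[seq(2, n, 2), ] <- twin2
  dimnames(dosage) <- list(sample_id, snp_ids)

  ## --- covariates ---------------------------------------------------------
  sex_pair <- stats::rbinom(np, 1, 0.5)
  sex <- rep(sex_pair, each = 2)
  dz_rows <- which(zygosity == "DZ" & seq_len(n) %% 2 == 0)
  sex[dz_rows] <- stats::rbinom(length(dz_rows), 1, 0.5)  # DZ co-twin resampled
  age <- rep(stats::runif(np, 18, 70), each = 2)
  age_at_trait <- age + stats::rnorm(n, 0, 1.5)
  cell_z <- stats::rnorm(n)
  cell_prop <- stats::plogis(-0.5 + 0.4 * cell_z)  # proportion in (0, 1)
  batch <- sample(c("b1", "b2"), n, replace = TRUE)

  ## --- methylation: correlated latent blocks + cell confounding -----------
  cpg_ids <- sprintf("cg%08d", seq_len(config$n_cpgs))
  block <- ceiling(seq_len(config$n_cpgs) / config$block_size)
  n_blocks <- max(block)
  u <- matrix(stats::rnorm(n * n_blocks), nrow = n)
  e <- matrix(stats::rnorm(n * config$n_cpgs), nrow = n)
  latent <- sqrt(config$block_rho) * u[, block, drop = FALSE] +
    sqrt(1 - config$block_rho) * e
  gamma <- stats::rnorm(config$n_cpgs, 0, 0.2)  # per-CpG cell loading
  latent <- latent + outer(cell_z, gamma)
  # gentle squash: beta values stay nearly affine in the latent scale, so
  # scores computed on either scale agree (mid-range beta values, as seen
  # at trait-associated CpGs)
  baseline <- stats::runif(config$n_cpgs, -1.5, 1.5)
  beta_vals <- stats::plogis(sweep(0.4 * latent, 2, baseline, "+"))
  dimnames(beta_vals) <- dimnames(latent) <- list(sample_id, cpg_ids)

  ## --- trait architecture -------------------------------------------------
  causal_cpgs <- cpg_ids[seq_len(config$n_causal_cpgs)]
  causal_snps <- snp_ids[seq_len(config$n_causal_snps)]
  w_cpg <- if (config$n_causal_cpgs) stats::rnorm(config$n_causal_cpgs) else numeric()
  w_snp <- if (config$n_causal_snps) stats::rnorm(config$n_causal_snps) else numeric()

  m_raw <- if (length(w_cpg)) drop(latent[, causal_cpgs, drop = FALSE] %*% w_cpg)
           else numeric(n)
  g_raw <- if (length(w_snp)) drop(dosage[, causal_snps, drop = FALSE] %*% w_snp)
           else numeric(n)
  c_raw <- cell_z + 0.5 * sex + 0.02 * age

  m_comp <- .scale_component(m_raw, config$r2_ms_true)
  g_comp <- .scale_component(g_raw, config$r2_pgs_true)
  c_comp <- .scale_component(c_raw, config$r2_cov_true)

  resid_var <- 1 - config$r2_ms_true - config$r2_pgs_true - config$r2_cov_true
  shared <- rep(stats::rnorm(np, 0, sqrt(config$env_rho * resid_var)), each = 2)
  noise_sd <- sqrt((1 - config$env_rho) * resid_var)
  signal <- m_comp$x + g_comp$x + c_comp$x + shared
  trait_cont <- signal + stats::rnorm(n, 0, noise_sd)
  liability <- signal + stats::rnorm(n, 0, noise_sd)
  threshold <- stats::qnorm(1 - config$prevalence)
  trait_bin <- as.integer(liability > threshold)

  ## --- genetic PCs (top-2 of the centred dosage matrix) -------------------
  dc <- scale(dosage, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(dc) / (n - 1), symmetric = TRUE)
  pcs <- dc %*% ev$vectors[, 1:2, drop = FALSE]
  pcs <- scale(pcs)

  pheno <- data.frame(
    sample_id = sample_id, family_id = family_id, zygosity = zygosity,
    sex = sex, age = age, age_at_trait = age_at_trait,
    cell_prop = cell_prop, batch = batch,
    PC1 = pcs[, 1], PC2 = pcs[, 2],
    trait_cont = trait_cont, trait_bin = trait_bin,
    stringsAsFactors = FALSE
  )

  truth <- list(
    causal_cpg_ids = causal_cpgs,
    cpg_effects = stats::setNames(w_cpg * m_comp$mult, causal_cpgs),
    causal_snp_ids = causal_snps,
    snp_effects = stats::setNames(w_snp * g_comp$mult, causal_snps),
    latent = latent,
    liability = liability,
    threshold = threshold,
    snp_freq = stats::setNames(freq, snp_ids),
    realized = c(
      r2_ms = stats::var(m_comp$x) / stats::var(trait_cont),
      r2_pgs = stats::var(g_comp$x) / stats::var(trait_cont),
      r2_cov = stats::var(c_comp$x) / stats::var(trait_cont)
    )
  )

  structure(list(beta = omics_matrix(beta_vals, "beta"),
                 dosage = omics_matrix(dosage, "dosage"),
                 pheno = pheno, alleles = alleles, truth = truth,
                 config = config),
            class = "sim_cohort")
}

#' Simulate discovery-cohort summary statistics
#'
#' Produces noisy EWAS and GWAS summary statistics around the cohort's true
#' marker effects: every marker's reported effect is its true effect (zero
#' for non-causal markers) plus Gaussian noise with standard deviation
#' `1/sqrt(n_discovery)`; the reported SE equals that SD and the p-value is
#' the two-sided Wald p. With `n_discovery = Inf` the reported effects equal
#' the true effects exactly.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param config optional [sim_config()]; defaults to the cohort's own.
#' @return A list with `ewas` (cpg_id, effect, se, p) and `gwas` (snp_id,
#'   effect_allele, other_allele, effect, se, p, maf) data.tables, both
#'   writable by the io module.
#' @export
simulate_discovery_stats <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "sim_cohort"))
  set.seed(config$seed + 1L)
  sd_noise <- if (is.finite(config$n_discovery)) 1 / sqrt(config$n_discovery) else 0

  noisy <- function(true_eff) {
    est <- true_eff + stats::rnorm(length(true_eff), 0, sd_noise)
    if (sd_noise > 0) {
      p <- 2 * stats::pnorm(-abs(est) / sd_noise)
      se <- rep(sd_noise, length(est))
    } else {
      p <- ifelse(est == 0, 1, .Machine$double.xmin)
      se <- rep(.Machine$double.xmin, length(est))  # SE must stay positive
    }
    list(effect = est, se = se, p = pmax(p, .Machine$double.xmin))
  }

  cpg_ids <- colnames(cohort$beta)
  true_cpg <- stats::setNames(numeric(length(cpg_ids)), cpg_ids)
  true_cpg[names(cohort$truth$cpg_effects)] <- cohort$truth$cpg_effects
  ew <- noisy(unname(true_cpg))
  ewas <- data.table::data.table(cpg_id = cpg_ids, effect = ew$effect,
                                 se = ew$se, p = ew$p)

  snp_ids <- colnames(cohort$dosage)
  true_snp <- stats::setNames(numeric(length(snp_ids)), snp_ids)
  true_snp[names(cohort$truth$snp_effects)] <- cohort$truth$snp_effects
  gw <- noisy(unname(true_snp))
  freq <- cohort$truth$snp_freq[snp_ids]
  gwas <- data.table::data.table(
    snp_id = snp_ids,
    effect_allele = cohort$alleles$counted_allele,
    other_allele = cohort$alleles$other_allele,
    effect = gw$effect, se = gw$se, p = gw$p,
    maf = pmin(freq, 1 - freq)
  )
  list(ewas = ewas, gwas = gwas)
}
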