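# Synthetic discovery + target cohort generator.
#
# Emulates the structure of a substance-dependence case/control cohort:
# LD-blocked biallelic genotypes, discovery GWAS summary statistics under a
# polygenic architecture, demographic covariates, and five ordinal substance
# involvement measures driven by a single latent liability factor with a
# genetic component. Everything is deterministic given the config seed.

SUBSTANCES <- c("alcohol", "nicotine", "cannabis", "cocaine", "opioids")

# Observed involvement-level counts used to calibrate default thresholds:
# rows = no/non-regular use, use 0 symptoms, 1-2, 3-5, 6-7 symptoms.
INVOLVEMENT_COUNTS <- matrix(
  c(258, 517, 591, 648, 559,
    595, 159, 499, 1120, 180,
    659, 1153, 312, 278, 168,
    1591, 416, 83, 131, 348,
    2043, 305, 45, 52, 124),
  nrow = 5, ncol = 5,
  dimnames = list(NULL, SUBSTANCES)
)

#' Default per-substance latent thresholds
#'
#' Cutpoints on the standard-normal latent-response scale chosen so that the
#' marginal category frequencies of each simulated substance match the
#' cohort-calibration counts (2573 participants): the k-th threshold is the
#' normal quantile of the cumulative proportion in the first k categories.
#'
#' @return A 4 x 5 numeric matrix of strictly ascending thresholds, one
#'   column per substance.
#' @export
default_thresholds <- function() {
  apply(INVOLVEMENT_COUNTS, 2, function(cnt) {
    stats::qnorm(cumsum(cnt[1:4]) / sum(cnt))
  })
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator. Defaults describe a
#' desk-scale cohort with the real sample's marginals: n = 2573 participants,
#' 56.2% female, age 38.67 (sd 9.76), study-of-origin sizes 927/557/1089, and
#' involvement thresholds calibrated to the published category counts.
#'
#' @param n_samples Number of target-cohort individuals.
#' @param n_snps Number of biallelic SNPs.
#' @param n_blocks Number of LD blocks; SNPs are split contiguously.
#' @param within_block_r Latent (copula) correlation of haplotypes within a
#'   block, in `[0, 1)`.
#' @param maf_range Range the per-SNP minor-allele frequency is drawn from,
#'   within `(0, 0.5]`.
#' @param n_discovery Effective discovery-GWAS sample size controlling the
#'   summary-statistic standard errors.
#' @param prop_causal Fraction of SNPs with nonzero true effect, in `(0, 1]`.
#' @param beta_sd Standard deviation of nonzero true log odds-ratios.
#' @param gamma Standardized effect of the true genetic score on the latent
#'   involvement factor.
#' @param loadings Five factor loadings in `(0, 1)`, one per substance
#'   (alcohol, nicotine, cannabis, cocaine, opioids).
#' @param thresholds 4 x 5 matrix of strictly ascending latent cutpoints per
#'   substance (see [default_thresholds()]).
#' @param covariate_effects Named standardized effects of covariates on the
#'   latent factor: `sex`, `age`, `pc1`..`pc3`, `study2`, `study3`.
#' @param missing_rate Genotype missingness fraction (missing completely at
#'   random), in `[0, 1)`.
#' @param seed Integer root seed; all stage streams derive from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_samples = 2573,
                       n_snps = 600,
                       n_blocks = 60,
                       within_block_r = 0.8,
                       maf_range = c(0.05, 0.5),
                       n_discovery = 50000,
                       prop_causal = 0.3,
                       beta_sd = 0.02,
                       gamma = 0.3,
                       loadings = c(alcohol = 0.80, nicotine = 0.65,
                                    cannabis = 0.80, cocaine = 0.80,
                                    opioids = 0.80),
                       thresholds = default_thresholds(),
                       covariate_effects = c(sex = -0.15, age = -0.10,
                                             pc1 = 0, pc2 = 0, pc3 = 0,
                                             study2 = 0.10, study3 = -0.10),
                       missing_rate = 0.01,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              n_blocks = as.integer(n_blocks),
              within_block_r = within_block_r, maf_range = maf_range,
              n_discovery = n_discovery, prop_causal = prop_causal,
              beta_sd = beta_sd, gamma = gamma, loadings = loadings,
              thresholds = thresholds, covariate_effects = covariate_effects,
              missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples > 0, cfg$n_snps > 0, cfg$n_blocks > 0)
  if (cfg$n_blocks > cfg$n_snps)
    stop("n_blocks must not exceed n_snps")
  if (cfg$within_block_r < 0 || cfg$within_block_r >= 1)
    stop("within_block_r must be in [0, 1)")
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (cfg$n_discovery <= 0) stop("n_discovery must be positive")
  if (cfg$prop_causal <= 0 || cfg$prop_causal > 1)
    stop("prop_causal must be in (0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (length(cfg$loadings) != 5 || any(cfg$loadings <= 0) ||
      any(cfg$loadings >= 1))
    stop("loadings must be 5 values in (0, 1)")
  thr <- cfg$thresholds
  if (!is.matrix(thr) || nrow(thr) != 4 || ncol(thr) != 5)
    stop("thresholds must be a 4 x 5 matrix")
  if (any(apply(thr, 2, diff) <= 0))
    stop("thresholds must be strictly ascending per substance")
  ss <- cfg$gamma^2 + sum(cfg$covariate_effects^2)
  if (ss >= 1)
    stop("gamma^2 + sum(covariate_effects^2) must be < 1 so the latent ",
         "factor can be scaled to unit variance")
  invisible(cfg)
}

# Per-stage RNG streams derived from the root seed (kept below 2^31).
derive_seed <- function(seed, stage) {
  (as.double(seed) * 1009 + stage) %% 2147483647
}

#' Simulate the variant population: positions, alleles, frequencies, blocks
#'
#' SNPs are split into contiguous LD blocks; blocks span < 250 kb, block
#' starts are 10 Mb apart on a rotating set of chromosomes, so distinct
#' blocks are always separated by > 500 kb. Alternate-allele frequencies
#' are drawn uniformly from `maf_range`. Only strand-unambiguous ref/alt
#' pairs are drawn, so strand never blocks harmonization of the generator's
#' own summary statistics.
#'
#' @param config A [sim_config()].
#' @return data.table: id, chrom, pos, allele_a, allele_b, maf, block.
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, 0L), {
    m <- config$n_snps
    block <- sort(rep_len(seq_len(config$n_blocks), m))
    chrom <- ((seq_len(config$n_blocks) - 1L) %% 22L) + 1L
    tier <- (seq_len(config$n_blocks) - 1L) %/% 22L
    pos <- integer(m)
    for (b in seq_len(config$n_blocks)) {
      idx <- which(block == b)
      start <- 1e6 + tier[b] * 1e7
      pos[idx] <- as.integer(round(start + seq(0, 240000,
                                               length.out = length(idx))))
    }
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    pairs <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                   c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
    pick <- sample.int(nrow(pairs), m, replace = TRUE)
    data.table::data.table(
      id = sprintf("snp%05d", seq_len(m)),
      chrom = chrom[block],
      pos = pos,
      allele_a = pairs[pick, 1],
      allele_b = pairs[pick, 2],
      maf = maf,
      block = block
    )
  })
}

#' Simulate LD-blocked biallelic genotypes
#'
#' Haplotypes are generated by Gaussian-copula thresholding: within each
#' block a latent standard normal with exchangeable correlation
#' `within_block_r` is dichotomized at the allele-frequency quantile, and two
#' haplotypes are summed to a 0/1/2 dosage of the alternate allele.
#' Supplying `meta` draws a fresh cohort from a fixed variant population
#' (fixed frequencies, positions, alleles), which is how replicate target
#' cohorts against one discovery GWAS are produced.
#'
#' @param config A [sim_config()].
#' @param meta Optional variant population from [simulate_population()];
#'   defaults to a fresh draw under the config seed.
#' @return List with `meta` and `dosage` (n_samples x n_snps integer matrix
#'   with NAs for missing calls; rows samples, columns variant ids).
#' @export
simulate_genotypes <- function(config, meta = NULL) {
  validate_sim_config(config)
  if (is.null(meta)) meta <- simulate_population(config)
  stopifnot(nrow(meta) == config$n_snps)
  withr::with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_samples
    m <- config$n_snps
    block <- meta$block
    dosage <- matrix(0L, n, m)
    cut <- stats::qnorm(meta$maf)
    r <- config$within_block_r
    for (h in 1:2) {
      for (b in unique(block)) {
        idx <- which(block == b)
        shared <- stats::rnorm(n)
        z <- sqrt(r) * shared +
          sqrt(1 - r) * matrix(stats::rnorm(n * length(idx)), n)
        dosage[, idx] <- dosage[, idx] +
          (z < rep(cut[idx], each = n)) * 1L
      }
    }
    if (config$missing_rate > 0) {
      miss <- stats::runif(n * m) < config$missing_rate
      dosage[miss] <- NA_integer_
    }
    dimnames(dosage) <- list(sprintf("sample%05d", seq_len(n)), meta$id)
    list(meta = meta, dosage = dosage)
  })
}

#' Simulate a discovery GWAS: population, architecture, summary statistics
#'
#' Bundles one draw of the variant population, the true polygenic
#' architecture, and the observed discovery summary statistics. Replicate
#' target cohorts are then drawn against this single fixed discovery via
#' `simulate_cohort(config, discovery = ...)`, mirroring a real design in
#' which one published GWAS is scored in many target samples.
#'
#' @param config A [sim_config()].
#' @return List: `meta`, `true_betas`, `sumstats`.
#' @export
simulate_discovery <- function(config) {
  meta <- simulate_population(config)
  true_betas <- simulate_true_betas(config)
  list(meta = meta, true_betas = true_betas,
       sumstats = simulate_discovery_stats(config, meta, true_betas))
}

#' Draw true per-SNP effects
#'
#' A random `prop_causal` fraction of SNPs receive normal log odds-ratio
#' effects with sd `beta_sd`; the rest are exactly zero.
#'
#' @param config A [sim_config()].
#' @return Numeric vector of length `n_snps`.
#' @export
simulate_true_betas <- function(config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, 2L), {
    m <- config$n_snps
    n_causal <- round(config$prop_causal * m)
    beta <- numeric(m)
    beta[sample.int(m, n_causal)] <- stats::rnorm(n_causal, 0, config$beta_sd)
    beta
  })
}

#' Simulate discovery GWAS summary statistics
#'
#' Observed log odds-ratios are the true effects plus sampling noise with
#' standard error `1 / sqrt(2 * n_discovery * p * (1 - p))`, the usual
#' large-sample SE of a per-allele effect at allele frequency p; p-values are
#' two-sided normal tails of beta / SE.
#'
#' @param config A [sim_config()].
#' @param meta Variant metadata from [simulate_genotypes()].
#' @param true_betas Vector of true effects, length `n_snps`.
#' @return data.table with columns SNP, CHR, BP, A1, A2, BETA, P (A1 is the
#'   effect allele = the alternate allele of the target genotypes).
#' @export
simulate_discovery_stats <- function(config, meta, true_betas) {
  validate_sim_config(config)
  if (length(true_betas) != config$n_snps)
    stop("true_betas must have length n_snps")
  withr::with_seed(derive_seed(config$seed, 3L), {
    p <- meta$maf
    se <- 1 / sqrt(2 * config$n_discovery * p * (1 - p))
    beta_hat <- true_betas + stats::rnorm(length(p), 0, se)
    z <- beta_hat / se
    data.table::data.table(
      SNP = meta$id, CHR = meta$chrom, BP = meta$pos,
      A1 = meta$allele_b, A2 = meta$allele_a,
      BETA = beta_hat, P = 2 * stats::pnorm(-abs(z))
    )
  })
}

#' Simulate demographic covariates
#'
#' Marginals follow the calibration cohort: sex Bernoulli(0.562) for female,
#' age Normal(38.67, 9.76^2), three ancestry PCs standard normal, and study
#' of origin multinomial with weights 927/557/1089.
#'
#' @param config A [sim_config()].
#' @return data.table with sample_id, sex (1 = female), age, pc1..pc3, study
#'   (factor levels study1..study3).
#' @export
simulate_covariates <- function(config) {
  validate_sim_config(config)
  withr::with_seed(derive_seed(config$seed, 4L), {
    n <- config$n_samples
    data.table::data.table(
      sample_id = sprintf("sample%05d", seq_len(n)),
      sex = stats::rbinom(n, 1, 0.562),
      age = stats::rnorm(n, 38.67, 9.76),
      pc1 = stats::rnorm(n), pc2 = stats::rnorm(n), pc3 = stats::rnorm(n),
      study = factor(sample(paste0("study", 1:3), n, replace = TRUE,
                            prob = c(927, 557, 1089) / 2573),
                     levels = paste0("study", 1:3))
    )
  })
}

#' Simulate ordinal substance-involvement measures
#'
#' Generative inverse of the one-factor measurement model: the latent
#' involvement factor is `gamma * standardized(true_score)` plus standardized
#' covariate effects plus a residual scaled so the factor has unit variance.
#' Each substance's latent response is `loading * factor` plus unique normal
#' error, and the observed level 0-4 counts how many of that substance's four
#' thresholds lie below the response.
#'
#' @param config A [sim_config()].
#' @param true_score Per-sample true genetic score (any scale; standardized
#'   internally).
#' @param covariates Covariate table from [simulate_covariates()].
#' @return List with `involvement` (data.table: sample_id plus one 0-4
#'   integer column per substance) and `truth` (list: true_score,
#'   latent_factor, gamma).
#' @export
simulate_involvement <- function(config, true_score, covariates) {
  validate_sim_config(config)
  n <- config$n_samples
  stopifnot(length(true_score) == n, nrow(covariates) == n)
  withr::with_seed(derive_seed(config$seed, 5L), {
    g <- as.numeric(scale(true_score))
    eff <- config$covariate_effects
    xc <- cbind(sex = covariates$sex, age = covariates$age,
                pc1 = covariates$pc1, pc2 = covariates$pc2,
                pc3 = covariates$pc3,
                study2 = as.integer(covariates$study == "study2"),
                study3 = as.integer(covariates$study == "study3"))
    xc <- scale(xc)
    xc[is.nan(xc)] <- 0  # constant column at tiny n
    lin <- config$gamma * g + drop(xc %*% eff[colnames(xc)])
    resid_sd <- sqrt(1 - config$gamma^2 - sum(eff^2))
    f <- lin + stats::rnorm(n, 0, resid_sd)
    lev <- matrix(0L, n, 5, dimnames = list(NULL, SUBSTANCES))
    for (s in seq_along(SUBSTANCES)) {
      lam <- config$loadings[s]
      ystar <- lam * f + stats::rnorm(n, 0, sqrt(1 - lam^2))
      lev[, s] <- rowSums(outer(ystar, config$thresholds[, s], `>`))
    }
    involvement <- data.table::data.table(sample_id = covariates$sample_id)
    for (s in SUBSTANCES) involvement[[s]] <- lev[, s]
    list(involvement = involvement,
         truth = list(true_score = true_score, latent_factor = f,
                      gamma = config$gamma))
  })
}

#' Simulate a complete cohort
#'
#' Runs all generator stages: genotypes, true effects, discovery summary
#' statistics, covariates, and involvement measures. With `discovery`
#' supplied (see [simulate_discovery()]), the variant population, true
#' effects, and summary statistics are held fixed and only the target
#' cohort (genotypes, covariates, involvement) is redrawn under the config
#' seed.
#'
#' @param config A [sim_config()].
#' @param discovery Optional fixed discovery bundle from
#'   [simulate_discovery()].
#' @return List with `meta`, `dosage`, `sumstats`, `covariates`,
#'   `involvement`, `truth` (true_betas, true_score, latent_factor, gamma).
#' @export
simulate_cohort <- function(config, discovery = NULL) {
  if (is.null(discovery)) discovery <- simulate_discovery(config)
  geno <- simulate_genotypes(config, discovery$meta)
  true_betas <- discovery$true_betas
  d <- geno$dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    na <- which(is.na(d), arr.ind = TRUE)
    d[na] <- mu[na[, 2]]
  }
  true_score <- drop(d %*% true_betas)
  sumstats <- discovery$sumstats
  covars <- simulate_covariates(config)
  inv <- simulate_involvement(config, true_score, covars)
  list(meta = geno$meta, dosage = geno$dosage, sumstats = sumstats,
       covariates = covars, involvement = inv$involvement,
       truth = c(list(true_betas = true_betas), inv$truth))
}

#' Calibrate the genetic effect to a target recovered association
#'
#' The standardized coefficient recovered by regressing the estimated GENSUB
#' factor score on the constructed PRS is attenuated twice relative to
#' `gamma`: by the imperfect correlation r between the PRS and the true
#' genetic score, and by the validity rho of the factor score for the latent
#' factor. This routine measures `r * rho` on pilot cohorts run
#' through the full pipeline and returns the `gamma` for which the
#' population-recovered coefficient equals `target_beta` (equivalently, the
#' recovered incremental R-squared equals `target_beta^2`, since the PRS is
#' generated independently of the covariates).
#'
#' @param config A [sim_config()]; its `gamma` is the pilot reference value.
#' @param target_beta Target standardized PRS coefficient on GENSUB.
#' @param discovery Fixed discovery bundle from [simulate_discovery()];
#'   defaults to the one implied by the config seed. Calibration and
#'   recovery replicates must share it.
#' @param n_pilot Pilot cohort size (default 10000).
#' @param n_rep Number of pilot cohorts averaged.
#' @param threshold PRS p-value threshold used in calibration and recovery.
#' @return List: `gamma` (calibrated value), `attenuation` (estimated mean
#'   `r * rho`), `r`, `rho` (per-pilot values).
#' @export
calibrate_gamma <- function(config, target_beta, discovery = NULL,
                            n_pilot = 10000, n_rep = 2, threshold = 0.5) {
  if (is.null(discovery)) discovery <- simulate_discovery(config)
  pilot_cfg <- config
  pilot_cfg$n_samples <- as.integer(n_pilot)
  r <- rho <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    pilot_cfg$seed <- as.integer(derive_seed(config$seed, 600L + i))
    validate_sim_config(pilot_cfg)
    sim <- simulate_cohort(pilot_cfg, discovery)
    prs <- cohort_prs(sim, threshold = threshold)
    r[i] <- abs(stats::cor(prs, sim$truth$true_score))
    tab <- as.matrix(sim$involvement[, -1, with = FALSE])
    fit <- fit_one_factor(tab)
    scores <- factor_scores(fit, tab)
    rho[i] <- abs(stats::cor(scores, sim$truth$latent_factor))
  }
  att <- mean(r * rho)
  gamma <- target_beta / att
  if (gamma^2 + sum(config$covariate_effects^2) >= 1)
    stop("calibrated gamma infeasible; increase discovery power or loadings")
  list(gamma = gamma, attenuation = att, r = r, rho = rho)
}

# PRS at one threshold for a simulated cohort: QC + harmonize + clump + score.
cohort_prs <- function(sim, threshold = 0.5,
                       qc = qc_params(), clump = clump_params()) {
  meta <- variant_qc_stats(sim$meta, sim$dosage)
  keep <- qc_filter(meta, qc)
  ss <- sim$sumstats[sim$sumstats$SNP %in% keep, ]
  hz <- harmonize(ss, meta[meta$id %in% keep, ])
  idx <- clump_variants(hz, sim$dosage, clump)
  prs_score(sim$dosage, hz[hz$SNP %in% idx, ], threshold)
}
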