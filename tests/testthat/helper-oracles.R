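# Independent oracles: deliberately naive reimplementations used only to
# check the package's optimized code paths.

# Hardy-Weinberg exact p by direct log-factorial enumeration of every
# heterozygote count compatible with the observed allele counts.
hwe_oracle <- function(aa, ab, bb) {
  n <- aa + ab + bb
  na <- 2 * aa + ab
  nb <- 2 * bb + ab
  rare <- min(na, nb)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    haa <- (na - h) / 2
    hbb <- (nb - h) / 2
    lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(ab, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Literal greedy clumping: plain loops, no vectorization tricks.
clump_oracle <- function(sumstats, dosage, r2_threshold = 0.10,
                         window_kb = 500) {
  ss <- as.data.frame(sumstats)
  ss <- ss[order(ss$P, ss$CHR, ss$BP), ]
  assigned <- rep(FALSE, nrow(ss))
  index <- character(0)
  for (i in seq_len(nrow(ss))) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    index <- c(index, ss$SNP[i])
    for (j in seq_len(nrow(ss))) {
      if (assigned[j]) next
      if (ss$CHR[j] != ss$CHR[i]) next
      if (abs(ss$BP[j] - ss$BP[i]) > window_kb * 1000) next
      r <- suppressWarnings(cor(dosage[, ss$SNP[i]], dosage[, ss$SNP[j]],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 >= r2_threshold) assigned[j] <- TRUE
    }
  }
  index
}

# A tiny aligned summary-statistics table plus matching dosage matrix with
# controllable LD, used by clumping and scoring tests.
make_ld_fixture <- function(n = 2000, p_values, positions, chrom = 1,
                            ld_with_first = NULL, seed = 42) {
  m <- length(p_values)
  withr::with_seed(seed, {
    base <- rbinom(n, 2, 0.3)
    dosage <- matrix(NA_integer_, n, m)
    for (j in seq_len(m)) {
      rho <- if (is.null(ld_with_first)) 0 else ld_with_first[j]
      flip <- runif(n) > rho
      dosage[, j] <- ifelse(flip, rbinom(n, 2, 0.3), base)
    }
    colnames(dosage) <- sprintf("v%02d", seq_len(m))
    rownames(dosage) <- sprintf("s%04d", seq_len(n))
    ss <- data.frame(SNP = colnames(dosage), CHR = chrom, BP = positions,
                     A1 = "A", A2 = "G", BETA = rnorm(m, 0, 0.05),
                     P = p_values)
    list(sumstats = ss, dosage = dosage)
  })
}

# Continuous one-factor data with known loadings (no discretization).
make_factor_data <- function(n, loadings, seed = 1) {
  withr::with_seed(seed, {
    f <- rnorm(n)
    x <- sapply(loadings, function(l) l * f + rnorm(n, 0, sqrt(1 - l^2)))
    colnames(x) <- paste0("ind", seq_along(loadings))
    list(x = x, f = f)
  })
}

# Small covariate table with the expected phenotype columns.
make_covar_table <- function(n, seed = 3) {
  withr::with_seed(seed, {
    data.frame(sample_id = sprintf("s%04d", seq_len(n)),
               sex = rbinom(n, 1, 0.5),
               age = rnorm(n, 40, 10),
               pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
               study = factor(sample(paste0("study", 1:3), n, TRUE)))
  })
}

# Desk-scale sim config for fast tests.
small_sim_config <- function(...) {
  sim_config(n_samples = 400, n_snps = 120, n_blocks = 12,
             n_discovery = 20000, seed = 5, ...)
}
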