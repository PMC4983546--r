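test_that("HWE exact test handles degenerate and reference cases", {
  expect_equal(hwe_exact_p(10, 0, 0), 1.0)
  expect_equal(hwe_exact_p(0, 1, 0), 1.0)
  expect_equal(hwe_exact_p(3, 5, 2), hwe_oracle(3, 5, 2), tolerance = 1e-12)
  expect_error(hwe_exact_p(-1, 0, 1), "counts")
  expect_error(hwe_exact_p(0, 0, 0), "positive")
})

test_that("HWE exact test matches enumeration on random large tables", {
  withr::with_seed(7, {
    for (i in 1:100) {
      n <- sample(1:3000, 1)
      aa <- sample(0:n, 1)
      ab <- sample(0:(n - aa), 1)
      bb <- n - aa - ab
      expect_equal(hwe_exact_p(aa, ab, bb), hwe_oracle(aa, ab, bb),
                   tolerance = 1e-9,
                   info = paste(aa, ab, bb))
    }
  })
})

test_that("variant_qc_stats computes call rate, MAF and HWE correctly", {
  dosage <- cbind(a = c(0L, 1L, 2L, 1L, NA),
                  b = c(2L, 2L, 2L, 2L, 2L),
                  c = c(0L, 0L, 1L, 1L, 2L))
  meta <- data.frame(id = c("a", "b", "c"), chrom = 1, pos = 1:3,
                     allele_a = "A", allele_b = "G")
  st <- variant_qc_stats(meta, dosage)
  expect_equal(st$call_rate, c(0.8, 1, 1))
  expect_equal(st$maf, c(0.5, 0, 0.4))
  expect_equal(st$hwe_p[2], 1)
  expect_equal(st$hwe_p[3], hwe_oracle(2, 2, 1))
})

test_that("qc_filter applies strict thresholds and the MHC exclusion", {
  meta <- data.frame(
    id = sprintf("v%02d", 1:10),
    chrom = c(1, 1, 1, 6, 6, 2, 2, 3, 3, 4),
    pos = c(1e6, 2e6, 3e6, 30e6, 40e6, 1e6, 2e6, 1e6, 2e6, 1e6),
    maf = c(0.02, rep(0.25, 9)),            # v01 fails MAF (strict >)
    call_rate = c(1, 0.98, rep(1, 8)),      # v02 fails call rate (strict >)
    hwe_p = c(1, 1, 1e-6, rep(1, 7))        # v03 fails HWE (strict >)
  )                                         # v04 inside MHC -> removed
  keep <- qc_filter(meta)
  expect_setequal(keep, c("v05", "v06", "v07", "v08", "v09", "v10"))
  # hand audit: each rule fails exactly one variant
  expect_false("v01" %in% keep)
  expect_false("v02" %in% keep)
  expect_false("v03" %in% keep)
  expect_false("v04" %in% keep)
  expect_true("v05" %in% keep)  # chr6 but outside 25-35 Mb
})

test_that("harmonize aligns effects to the counted allele", {
  meta <- data.frame(id = c("d", "s", "c", "cs", "amb", "mis"),
                     allele_a = c("G", "A", "G", "A", "T", "C"),
                     allele_b = c("A", "G", "A", "G", "A", "A"))
  ss <- data.frame(SNP = meta$id, CHR = 1, BP = 1:6,
                   A1 = c("A", "A", "T", "T", "A", "A"),
                   A2 = c("G", "G", "C", "C", "T", "G"),
                   BETA = rep(0.5, 6), P = rep(0.01, 6))
  out <- harmonize(ss, meta)
  expect_setequal(out$SNP, c("d", "s", "c", "cs"))
  expect_equal(out$BETA[match(c("d", "c"), out$SNP)], c(0.5, 0.5))
  expect_equal(out$BETA[match(c("s", "cs"), out$SNP)], c(-0.5, -0.5))
  expect_equal(attr(out, "n_dropped"), 2)
  # effect allele rewritten to the counted (allele_b) allele
  expect_equal(out$A1, meta$allele_b[match(out$SNP, meta$id)])
  expect_error(harmonize(rbind(ss, ss[1, ]), meta), "duplicate")
})

test_that("clumping matches the literal greedy oracle on LD fixtures", {
  fx <- make_ld_fixture(
    n = 1500,
    p_values = c(0.02, 0.001, 0.5, 0.04, 0.9),
    positions = c(1e6, 1.1e6, 1.2e6, 1.3e6, 1.4e6),
    ld_with_first = c(1, 0.9, 0.85, 0.1, 0.05))
  got <- clump_variants(fx$sumstats, fx$dosage)
  expect_setequal(got, clump_oracle(fx$sumstats, fx$dosage))
  # index SNPs have the lowest p in their clump: the first index is the
  # global minimum
  expect_equal(got[1], fx$sumstats$SNP[which.min(fx$sumstats$P)])
})

test_that("clumping is invariant to input row order", {
  fx <- make_ld_fixture(
    n = 1000,
    p_values = c(0.3, 0.001, 0.2, 0.04, 0.6, 0.01),
    positions = c(1e6, 1.05e6, 1.1e6, 1.15e6, 1.2e6, 1.25e6),
    ld_with_first = c(1, 0.8, 0.8, 0.2, 0.9, 0.3), seed = 77)
  a <- clump_variants(fx$sumstats, fx$dosage)
  shuf <- fx$sumstats[c(4, 2, 6, 1, 5, 3), ]
  b <- clump_variants(shuf, fx$dosage)
  expect_setequal(a, b)
})

test_that("variants beyond the window are never clumped together", {
  n <- 500
  withr::with_seed(10, {
    x <- rbinom(n, 2, 0.4)
    dosage <- cbind(v1 = x, v2 = x)  # r2 = 1
  })
  ss <- data.frame(SNP = c("v1", "v2"), CHR = 1, BP = c(1e6, 1.6001e6),
                   A1 = "A", A2 = "G", BETA = 0.1, P = c(0.01, 0.5))
  expect_setequal(clump_variants(ss, dosage), c("v1", "v2"))
  ss$BP <- c(1e6, 1.4e6)  # inside the 500 kb window
  expect_equal(clump_variants(ss, dosage), "v1")
})

test_that("monomorphic variants never clump (r2 treated as 0)", {
  dosage <- cbind(v1 = c(0L, 1L, 2L, 1L), v2 = c(1L, 1L, 1L, 1L))
  ss <- data.frame(SNP = c("v1", "v2"), CHR = 1, BP = c(1e6, 1.1e6),
                   A1 = "A", A2 = "G", BETA = 0.1, P = c(0.01, 0.5))
  expect_setequal(clump_variants(ss, dosage), c("v1", "v2"))
})

test_that("score formula matches hand computation", {
  # one variant, beta = ln 2, dosage = 2 -> 2 ln 2
  ss1 <- data.frame(SNP = "v1", BETA = log(2), P = 0.01)
  d1 <- matrix(2L, 1, 1, dimnames = list("s1", "v1"))
  expect_equal(unname(prs_score(d1, ss1, 0.05)), 2 * log(2),
               ignore_attr = TRUE)

  # 3 variants x 2 samples, spreadsheet oracle
  d <- matrix(c(0L, 2L, 1L, 1L, 2L, 0L), 2, 3,
              dimnames = list(c("s1", "s2"), c("v1", "v2", "v3")))
  ss <- data.frame(SNP = c("v1", "v2", "v3"), BETA = c(0.2, -0.1, 0.4),
                   P = c(0.001, 0.01, 0.04))
  expected <- c(s1 = (0 * 0.2 + 1 * -0.1 + 2 * 0.4) / 3,
                s2 = (2 * 0.2 + 1 * -0.1 + 0 * 0.4) / 3)
  expect_equal(prs_score(d, ss, 0.05), expected,
               ignore_attr = "n_snps_used")

  # all betas zero -> all scores zero
  ss$BETA <- 0
  expect_true(all(prs_score(d, ss, 0.05) == 0))

  # empty threshold errors and names the cutoff
  expect_error(prs_score(d, ss, 0.0001), "0.0001")
})

test_that("missing dosages are mean-imputed as 2x allele frequency", {
  d <- matrix(c(0L, 2L, NA, 2L), 4, 1, dimnames = list(NULL, "v1"))
  ss <- data.frame(SNP = "v1", BETA = 1, P = 0.001)
  s <- prs_score(d, ss, 0.05)
  expect_equal(unname(s[3]), mean(c(0, 2, 2)))  # imputed to 2 * (4/6)/2 * 2
})

test_that("allele swap shifts scores by a constant and leaves OLS invariant", {
  fx <- make_ld_fixture(n = 300, p_values = runif(6, 0.001, 0.4),
                        positions = seq(1e6, 6e6, by = 1e6), seed = 55)
  ss <- fx$sumstats
  s1 <- prs_score(fx$dosage, ss, 0.5)
  ss2 <- ss
  ss2$BETA <- -ss$BETA
  s2 <- prs_score(2L - fx$dosage, ss2, 0.5)
  expect_equal(var(s1 - s2), 0, tolerance = 1e-18)
  withr::with_seed(1, y <- rnorm(300))
  f1 <- ols_incremental(y, s1)
  f2 <- ols_incremental(y, s2)
  expect_equal(f1$beta_std, f2$beta_std, tolerance = 1e-10)
  expect_equal(f1$r2_inc, f2$r2_inc, tolerance = 1e-10)
})

test_that("profiles nest across thresholds and ignore column order", {
  cfg <- small_sim_config()
  sim <- simulate_cohort(cfg)
  hz <- harmonize(sim$sumstats, sim$meta)
  idx <- clump_variants(hz, sim$dosage)
  aligned <- hz[hz$SNP %in% idx, ]
  prof <- build_profiles(sim$dosage, aligned)
  expect_equal(prof$thresholds, PRS_THRESHOLDS)
  expect_true(all(diff(prof$n_snps_used) >= 0))
  expect_equal(prof$n_snps_used[10], nrow(aligned))  # p <= 1 includes all
  # permuting variant columns leaves scores unchanged
  perm <- sample(ncol(sim$dosage))
  prof2 <- build_profiles(sim$dosage[, perm], aligned)
  expect_equal(prof$scores, prof2$scores)
})

test_that("VCF round-trips through our reader and VariantAnnotation", {
  cfg <- small_sim_config(missing_rate = 0.05)
  g <- simulate_genotypes(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g$meta, g$dosage, path)
  back <- read_vcf_dosage(path)
  expect_equal(back$dosage, g$dosage)
  expect_equal(back$meta$id, g$meta$id)
  expect_equal(back$meta$allele_a, g$meta$allele_a)

  skip_if_not_installed("VariantAnnotation")
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  gt <- VariantAnnotation::geno(vcf)$GT
  alt_count <- matrix(NA_integer_, nrow(gt), ncol(gt))
  alt_count[gt == "0/0"] <- 0L
  alt_count[gt == "0/1"] <- 1L
  alt_count[gt == "1/1"] <- 2L
  expect_equal(unname(t(alt_count)), unname(g$dosage))
})

test_that("dosage and sumstats TSV round-trips preserve content", {
  cfg <- small_sim_config(missing_rate = 0.1)
  g <- simulate_genotypes(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(g$dosage, path)
  expect_equal(read_dosage_tsv(path), g$dosage)

  ss <- data.frame(SNP = c("a", "b"), CHR = 1:2, BP = c(100L, 200L),
                   A1 = "A", A2 = "G", OR = c(1.5, 0.8), P = c(0.1, 0.9))
  sp <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(ss, sp, sep = "\t")
  got <- read_sumstats(sp)
  expect_equal(got$BETA, log(c(1.5, 0.8)))
  expect_error(read_sumstats(withr::local_tempfile(lines = "SNP\tP\nx\t0.5")),
               "missing columns")
})
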