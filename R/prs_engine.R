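# Variant QC, allele harmonization, p-value-informed LD clumping, and
# thresholded polygenic score computation.

#' The fixed p-value threshold ladder
#'
#' Scores are built at these ten discovery p-value cutoffs.
#' @export
PRS_THRESHOLDS <- c(0.0001, 0.001, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 1.0)

#' QC thresholds
#'
#' Defaults are the analysis values: MAF > 0.02, call rate > 0.98, HWE exact
#' p > 1e-6 (all strict), and exclusion of the MHC region (chr6:25-35 Mb).
#'
#' @param maf_min Minimum minor-allele frequency (exclusive).
#' @param call_rate_min Minimum call rate (exclusive).
#' @param hwe_p_min Minimum Hardy-Weinberg exact p-value (exclusive).
#' @param mhc_chrom,mhc_start,mhc_end Excluded region (inclusive bounds).
#' @return A `qc_params` list.
#' @export
qc_params <- function(maf_min = 0.02, call_rate_min = 0.98,
                      hwe_p_min = 1e-6, mhc_chrom = 6,
                      mhc_start = 25000000, mhc_end = 35000000) {
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min, mhc_chrom = mhc_chrom,
                 mhc_start = mhc_start, mhc_end = mhc_end),
            class = "qc_params")
}

#' Clumping parameters
#'
#' @param r2_threshold Squared-correlation cutoff for assigning a variant to
#'   an index SNP's clump (default 0.10).
#' @param window_kb Index-centered window half-width in kb (default 500).
#' @return A `clump_params` list.
#' @export
clump_params <- function(r2_threshold = 0.10, window_kb = 500) {
  stopifnot(r2_threshold > 0, r2_threshold < 1, window_kb > 0)
  structure(list(r2_threshold = r2_threshold, window_kb = window_kb),
            class = "clump_params")
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg genotype proportions: given the
#' observed allele counts, the p-value is the sum of probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count (Wigginton-style mid-less enumeration, computed with a
#' stable recurrence).
#'
#' @param n_hom_a,n_het,n_hom_b Genotype counts (AA, AB, BB).
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_hom_a, n_het, n_hom_b) {
  if (any(c(n_hom_a, n_het, n_hom_b) < 0)) stop("genotype counts must be >= 0")
  n <- n_hom_a + n_het + n_hom_b
  if (n == 0) stop("total genotype count must be positive")
  n_a <- 2 * n_hom_a + n_het
  n_b <- 2 * n_hom_b + n_het
  rare <- min(n_a, n_b)
  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  mid <- which.min(abs(hets - n_a * n_b / (2 * n)))[1]
  probs[mid] <- 1
  # upward recurrence: P(h+2)/P(h) = 4 * nAA(h) * nBB(h) / ((h+2)(h+1))
  if (mid < length(hets)) {
    for (i in mid:(length(hets) - 1)) {
      h <- hets[i]
      haa <- (n_a - h) / 2
      hbb <- (n_b - h) / 2
      probs[i + 1] <- probs[i] * 4 * haa * hbb / ((h + 2) * (h + 1))
    }
  }
  if (mid > 1) {
    for (i in mid:2) {
      h <- hets[i]
      probs[i - 1] <- probs[i] * h * (h - 1) /
        (4 * ((n_a - h) / 2 + 1) * ((n_b - h) / 2 + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

#' Per-variant QC statistics from a dosage matrix
#'
#' Adds call rate, minor-allele frequency, and Hardy-Weinberg exact p to the
#' variant metadata, computed from the 0/1/2 dosages (NA = missing call).
#'
#' @param meta Variant metadata (id, chrom, pos, alleles).
#' @param dosage Samples x variants matrix, entries 0/1/2/NA.
#' @return Copy of `meta` with columns call_rate, maf, hwe_p.
#' @export
variant_qc_stats <- function(meta, dosage) {
  stopifnot(ncol(dosage) == nrow(meta))
  out <- data.table::as.data.table(meta)
  n <- nrow(dosage)
  n0 <- colSums(dosage == 0, na.rm = TRUE)
  n1 <- colSums(dosage == 1, na.rm = TRUE)
  n2 <- colSums(dosage == 2, na.rm = TRUE)
  called <- n0 + n1 + n2
  freq_b <- (n1 + 2 * n2) / (2 * pmax(called, 1))
  out$call_rate <- called / n
  out$maf <- pmin(freq_b, 1 - freq_b)
  out$hwe_p <- vapply(seq_len(nrow(meta)), function(j) {
    if (called[j] == 0) return(1)
    hwe_exact_p(n0[j], n1[j], n2[j])
  }, numeric(1))
  out
}

#' Variant quality-control filter
#'
#' Retains variants with MAF, call rate and HWE exact p strictly above their
#' thresholds and outside the MHC exclusion region (inclusive bounds).
#'
#' @param meta Metadata with call_rate, maf, hwe_p (see
#'   [variant_qc_stats()]).
#' @param params A [qc_params()].
#' @return Character vector of retained variant ids (possibly empty).
#' @export
qc_filter <- function(meta, params = qc_params()) {
  keep <- meta$maf > params$maf_min &
    meta$call_rate > params$call_rate_min &
    meta$hwe_p > params$hwe_p_min &
    !(meta$chrom == params$mhc_chrom &
        meta$pos >= params$mhc_start & meta$pos <= params$mhc_end)
  if (anyNA(keep)) stop("NA in QC statistics; run variant_qc_stats first")
  meta$id[keep]
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary statistics to target-cohort alleles
#'
#' Matches discovery and target variants by id and aligns the effect to the
#' target's counted allele (`allele_b` of the metadata, the allele the
#' dosage matrix counts). Direct matches keep the effect; swapped alleles
#' negate it; strand-complement matches are resolved the same way after
#' complementing; strand-ambiguous pairs (A/T, C/G) and irreconcilable
#' allele pairs are dropped.
#'
#' @param sumstats data.frame with SNP, A1 (effect allele), A2, BETA, P
#'   (CHR/BP carried through if present).
#' @param meta Target variant metadata (id, allele_a, allele_b).
#' @return data.table of aligned rows: SNP, CHR, BP, A1, A2, BETA, P with
#'   BETA expressed per copy of the target counted allele; attribute
#'   `n_dropped` records discarded variants.
#' @export
harmonize <- function(sumstats, meta) {
  ss <- data.table::as.data.table(sumstats)
  if (anyDuplicated(ss$SNP)) stop("duplicate variant ids in summary statistics")
  if (anyDuplicated(meta$id)) stop("duplicate variant ids in target metadata")
  m <- match(ss$SNP, meta$id)
  ss <- ss[!is.na(m)]
  tg <- meta[m[!is.na(m)], ]
  a1 <- toupper(ss$A1); a2 <- toupper(ss$A2)
  ta <- toupper(tg$allele_a); tb <- toupper(tg$allele_b)
  amb <- is_ambiguous(a1, a2)
  direct <- a1 == tb & a2 == ta
  swap <- a1 == ta & a2 == tb
  c1 <- COMPLEMENT[a1]; c2 <- COMPLEMENT[a2]
  comp <- c1 == tb & c2 == ta
  comp_swap <- c1 == ta & c2 == tb
  keep_sign <- !amb & (direct | (!direct & !swap & comp))
  flip_sign <- !amb & (swap | (!direct & !swap & !comp & comp_swap))
  keep <- keep_sign | flip_sign
  out <- ss[keep]
  out$BETA <- ifelse(flip_sign[keep], -out$BETA, out$BETA)
  out$A1 <- tb[keep]
  out$A2 <- ta[keep]
  data.table::setattr(out, "n_dropped", sum(!keep))
  out
}

#' p-value-informed LD clumping
#'
#' Greedy clumping: repeatedly take the lowest-p unassigned variant as an
#' index and assign to its clump every unassigned variant on the same
#' chromosome within `window_kb` whose genotype squared correlation with the
#' index is at least `r2_threshold`. Ties on p break by ascending chromosome
#' then position. r-squared is computed on pairwise-complete dosages; an
#' undefined correlation (monomorphic variant) counts as 0 and the variant
#' is never absorbed into another clump.
#'
#' @param sumstats Aligned summary statistics (SNP, CHR, BP, P).
#' @param dosage Samples x variants dosage matrix with variant-id columns.
#' @param params A [clump_params()].
#' @return Character vector of index variant ids, in selection order.
#' @export
clump_variants <- function(sumstats, dosage, params = clump_params()) {
  ss <- data.table::as.data.table(sumstats)
  if (!all(ss$SNP %in% colnames(dosage)))
    stop("all summary-statistic variants must be present in the dosage matrix")
  if (any(!is.finite(ss$P))) stop("p-values must be finite")
  ord <- order(ss$P, ss$CHR, ss$BP)
  ss <- ss[ord]
  assigned <- logical(nrow(ss))
  idx_ids <- character(0)
  win <- params$window_kb * 1000
  for (i in seq_len(nrow(ss))) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    idx_ids <- c(idx_ids, ss$SNP[i])
    cand <- which(!assigned & ss$CHR == ss$CHR[i] &
                    abs(ss$BP - ss$BP[i]) <= win)
    if (!length(cand)) next
    x <- dosage[, ss$SNP[i]]
    r2 <- vapply(cand, function(j) {
      r <- suppressWarnings(
        stats::cor(x, dosage[, ss$SNP[j]], use = "pairwise.complete.obs"))
      if (is.na(r)) 0 else r^2
    }, numeric(1))
    assigned[cand[r2 >= params$r2_threshold]] <- TRUE
  }
  idx_ids
}

#' Polygenic score at one p-value threshold
#'
#' Includes variants with discovery p strictly below the threshold; each
#' individual's score is the sum of (log odds-ratio x counted-allele dosage)
#' over included variants, divided by the number of included variants.
#' Missing dosages are mean-imputed as twice the counted-allele frequency
#' before weighting.
#'
#' @param dosage Samples x variants dosage matrix (variant-id columns).
#' @param sumstats Aligned summary statistics (SNP, BETA, P) restricted to
#'   QC-passing, clumped variants.
#' @param threshold p-value cutoff, one of [PRS_THRESHOLDS] (1.0 includes
#'   everything since p <= 1 < is replaced by p <= 1; see Details).
#' @return Named numeric vector of per-sample scores; attribute
#'   `n_snps_used` gives the number of contributing variants.
#' @details Inclusion is `P < threshold` except at the terminal threshold
#'   1.0, where `P <= 1` includes all variants (p-values equal to 1 occur).
#' @export
prs_score <- function(dosage, sumstats, threshold) {
  ss <- data.table::as.data.table(sumstats)
  inc <- if (threshold >= 1) ss$P <= 1 else ss$P < threshold
  ss <- ss[inc]
  m <- nrow(ss)
  if (m == 0)
    stop(sprintf("no variants with p < %g contribute to the score", threshold))
  d <- dosage[, ss$SNP, drop = FALSE]
  if (anyNA(d)) {
    freq <- colMeans(d, na.rm = TRUE) / 2
    na <- which(is.na(d), arr.ind = TRUE)
    d[na] <- 2 * freq[na[, 2]]
  }
  out <- drop(d %*% ss$BETA) / m
  attr(out, "n_snps_used") <- m
  out
}

#' PRS profiles across the full threshold ladder
#'
#' @param dosage Samples x variants dosage matrix.
#' @param sumstats Aligned, QC'd, clumped summary statistics.
#' @param thresholds p-value cutoffs (default [PRS_THRESHOLDS]).
#' @return A `prs_profile`: list with `scores` (samples x thresholds
#'   matrix), `n_snps_used` (per threshold), `thresholds`.
#' @export
build_profiles <- function(dosage, sumstats, thresholds = PRS_THRESHOLDS) {
  thresholds <- sort(thresholds)
  scores <- matrix(NA_real_, nrow(dosage), length(thresholds),
                   dimnames = list(rownames(dosage),
                                   paste0("p", thresholds)))
  n_used <- integer(length(thresholds))
  for (k in seq_along(thresholds)) {
    s <- prs_score(dosage, sumstats, thresholds[k])
    scores[, k] <- s
    n_used[k] <- attr(s, "n_snps_used")
  }
  structure(list(scores = scores, n_snps_used = n_used,
                 thresholds = thresholds),
            class = "prs_profile")
}

#' @export
print.prs_profile <- function(x, ...) {
  cat("PRS profile:", nrow(x$scores), "samples x", length(x$thresholds),
      "thresholds\n")
  print(data.frame(threshold = x$thresholds, n_snps_used = x$n_snps_used))
  invisible(x)
}
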