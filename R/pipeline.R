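# End-to-end orchestration: simulate (or load) -> QC -> clump -> score ->
# CFA -> associate -> permute -> report, with a checksum manifest.

#' Pipeline run configuration
#'
#' Exactly one of `paths` (sumstats / genotypes / phenotypes files) or
#' `synthetic` (a [sim_config()]) must be supplied. All analysis parameter
#' defaults are the published pipeline values: MAF > 0.02, call rate >
#' 0.98, HWE p > 1e-6, clumping r2 = 0.10 within 500 kb, the ten p-value
#' thresholds 0.0001 ... 1.0, and 10,000 permutations at alpha = 0.05.
#'
#' @param synthetic A [sim_config()] for synthetic mode, or NULL.
#' @param paths Named list (sumstats, genotypes, phenotypes) of input files
#'   for real-data mode, or NULL. `genotypes` may be a `.vcf` or a dosage
#'   TSV.
#' @param qc A [qc_params()].
#' @param clump A [clump_params()].
#' @param thresholds PRS p-value cutoffs.
#' @param perm A [perm_config()].
#' @param perm_family "multinom" (the level-wise multinomial z family, as in
#'   the published analysis) or "ols" (the PRS-GENSUB screen; far cheaper).
#' @param multinom_thresholds Thresholds at which multinomial fits are run.
#' @param substances Substance columns to analyse (>= 1 required).
#' @param outdir Output directory (created if needed).
#' @param seed Root seed (required in synthetic mode).
#' @return A validated `run_config` list.
#' @export
run_config <- function(synthetic = NULL, paths = NULL,
                       qc = qc_params(), clump = clump_params(),
                       thresholds = PRS_THRESHOLDS,
                       perm = perm_config(),
                       perm_family = c("multinom", "ols"),
                       multinom_thresholds = 0.5,
                       substances = SUBSTANCES,
                       outdir = "polycomorb_run", seed = NULL) {
  perm_family <- match.arg(perm_family)
  if (is.null(synthetic) == is.null(paths))
    stop("provide exactly one of 'synthetic' or 'paths'")
  if (!is.null(paths)) {
    need <- c("sumstats", "genotypes", "phenotypes")
    if (!all(need %in% names(paths)))
      stop("paths must name: ", paste(need, collapse = ", "))
  }
  if (!is.null(synthetic) && is.null(seed))
    stop("a seed is required in synthetic mode")
  if (length(substances) < 1) stop("at least one substance column required")
  structure(list(synthetic = synthetic, paths = paths, qc = qc,
                 clump = clump, thresholds = thresholds, perm = perm,
                 perm_family = perm_family,
                 multinom_thresholds = multinom_thresholds,
                 substances = substances, outdir = outdir, seed = seed),
            class = "run_config")
}

atomic_move <- function(tmp, final) {
  if (!file.rename(tmp, final)) stop("could not move output to ", final)
  final
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full pipeline
#'
#' Executes every stage in dependency order, writing result tables under
#' `config$outdir` and returning a manifest of parameters, per-stage wall
#' time, and md5 checksums of every output (identical config + seed implies
#' identical checksums for all outputs).
#'
#' @param config A [run_config()].
#' @return A `run_manifest` list (also written as `manifest.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  timings <- numeric(0)
  emit <- function(writer, name) {
    tmp <- file.path(config$outdir, paste0(".", name, ".tmp"))
    writer(tmp)
    atomic_move(tmp, file.path(config$outdir, name))
    outputs <<- c(outputs, name)
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    stage_log(stage, sprintf("done in %.2fs", timings[[stage]]))
    res
  }

  # ---- input ----
  inp <- timed("input", {
    if (!is.null(config$synthetic)) {
      sim_cfg <- config$synthetic
      sim_cfg$seed <- as.integer(derive_seed(config$seed, 11L))
      sim <- simulate_cohort(sim_cfg)
      emit(function(p) data.table::fwrite(sim$sumstats, p, sep = "\t"),
           "sumstats.tsv")
      emit(function(p) write_dosage_tsv(sim$dosage, p), "dosages.tsv")
      emit(function(p) write_phenotypes(sim$covariates, sim$involvement, p),
           "phenotypes.tsv")
      list(meta = sim$meta, dosage = sim$dosage, sumstats = sim$sumstats,
           pheno = merge(sim$covariates, sim$involvement, by = "sample_id",
                         sort = FALSE))
    } else {
      gt <- if (grepl("\\.vcf$", config$paths$genotypes)) {
        read_vcf_dosage(config$paths$genotypes)
      } else {
        d <- read_dosage_tsv(config$paths$genotypes)
        list(meta = NULL, dosage = d)
      }
      ss <- read_sumstats(config$paths$sumstats)
      if (is.null(gt$meta)) {
        m <- match(colnames(gt$dosage), ss$SNP)
        if (anyNA(m)) stop("dosage variants missing from summary statistics")
        gt$meta <- data.table::data.table(
          id = colnames(gt$dosage), chrom = ss$CHR[m], pos = ss$BP[m],
          allele_a = ss$A2[m], allele_b = ss$A1[m])
      }
      pheno <- data.table::fread(config$paths$phenotypes, sep = "\t")
      need <- c("sample_id", "sex", "age", "pc1", "pc2", "pc3", "study",
                config$substances)
      miss <- setdiff(need, names(pheno))
      if (length(miss))
        stop("phenotype table missing columns: ", paste(miss, collapse = ", "))
      list(meta = gt$meta, dosage = gt$dosage, sumstats = ss, pheno = pheno)
    }
  })

  # ---- qc ----
  meta_qc <- timed("qc", {
    mq <- variant_qc_stats(inp$meta, inp$dosage)
    keep <- qc_filter(mq, config$qc)
    mq$qc_pass <- mq$id %in% keep
    emit(function(p) data.table::fwrite(mq, p, sep = "\t"), "qc_report.tsv")
    mq
  })

  # ---- clump ----
  aligned <- timed("clump", {
    keep <- meta_qc$id[meta_qc$qc_pass]
    hz <- harmonize(inp$sumstats[inp$sumstats$SNP %in% keep, ],
                    meta_qc[meta_qc$id %in% keep, ])
    idx <- clump_variants(hz, inp$dosage, config$clump)
    hz$clump_index <- hz$SNP %in% idx
    emit(function(p) data.table::fwrite(
      hz[, c("SNP", "BETA", "P", "clump_index")], p, sep = "\t"),
      "clumped.tsv")
    hz[hz$clump_index == TRUE, ]
  })

  # ---- score ----
  profile <- timed("score", {
    pr <- build_profiles(inp$dosage, aligned, config$thresholds)
    emit(function(p) write_profiles(pr, p), "profiles.tsv")
    pr
  })

  # ---- cfa ----
  cfa <- timed("cfa", {
    tab <- as.matrix(inp$pheno[, config$substances, with = FALSE])
    if (length(config$substances) < 3)
      stop("at least 3 substance indicators are required to fit the factor")
    fit <- fit_one_factor(tab)
    scores <- factor_scores(fit, tab)
    emit(function(p) jsonlite::write_json(
      list(loadings = fit$loadings, uniquenesses = fit$uniquenesses,
           chisq = fit$chisq, df = fit$df,
           baseline_chisq = fit$baseline_chisq, baseline_df = fit$baseline_df,
           cfi = unname(fit$cfi), rmsea = unname(fit$rmsea), n = fit$n),
      p, auto_unbox = TRUE, digits = NA), "factor.json")
    emit(function(p) data.table::fwrite(
      data.table::data.table(sample_id = inp$pheno$sample_id,
                             gensub = scores), p, sep = "\t"), "gensub.tsv")
    list(fit = fit, scores = scores)
  })

  covars <- build_covariates(inp$pheno)

  # ---- assoc ----
  assoc <- timed("assoc", {
    ols <- do.call(rbind, lapply(seq_along(config$thresholds), function(k) {
      r <- ols_incremental(cfa$scores, profile$scores[, k], covars)
      data.frame(threshold = config$thresholds[k], beta_std = r$beta_std,
                 r2_inc = r$r2_inc, pvalue = r$pvalue, n = r$n)
    }))
    rows <- list(); contr <- list()
    for (thr in config$multinom_thresholds) {
      k <- which(abs(config$thresholds - thr) < 1e-12)
      if (!length(k)) stop("multinom threshold not in threshold list: ", thr)
      for (s in config$substances) {
        lev <- inp$pheno[[s]]
        fit <- multinomial_fit(lev, profile$scores[, k], covars)
        adj <- adjusted_rerun(lev, profile$scores[, k], covars, cfa$scores)
        for (mod in c("raw", "gensub_adjusted")) {
          f <- if (mod == "raw") fit else adj
          rows[[length(rows) + 1]] <- data.frame(
            substance = s, threshold = thr, level = f$prs$level,
            b = f$prs$b, se = f$prs$se, z = f$prs$z, or = f$prs$or,
            model = mod)
        }
        w <- wald_all_pairs(fit)
        w$substance <- s; w$threshold <- thr
        contr[[length(contr) + 1]] <- w
      }
    }
    mn <- do.call(rbind, rows)
    emit(function(p) data.table::fwrite(ols, p, sep = "\t"),
         "ols_results.tsv")
    emit(function(p) data.table::fwrite(mn, p, sep = "\t"),
         "assoc_results.tsv")
    emit(function(p) data.table::fwrite(do.call(rbind, contr), p,
                                        sep = "\t"), "contrasts.tsv")
    list(ols = ols, multinom = mn)
  })

  # ---- permute ----
  thr <- timed("permute", {
    pcfg <- config$perm
    pcfg$seed <- as.integer(derive_seed(config$seed %||% pcfg$seed, 13L))
    tests <- if (config$perm_family == "ols") {
      lapply(seq_along(config$thresholds), function(k)
        perm_test("ols", cfa$scores, k, covars,
                  label = paste0("gensub:p", config$thresholds[k])))
    } else {
      specs <- list()
      for (t0 in config$multinom_thresholds) {
        k <- which(abs(config$thresholds - t0) < 1e-12)
        for (s in config$substances) {
          lev <- inp$pheno[[s]]
          for (l in seq_len(length(unique(lev)) - 1)) {
            specs[[length(specs) + 1]] <- perm_test(
              "multinom", lev, k, covars, level = l,
              label = sprintf("%s:p%s:level%d", s, t0, l))
          }
        }
      }
      specs
    }
    pt <- permute_family(profile$scores, tests, pcfg)
    emit(function(p) jsonlite::write_json(
      list(z_crit = pt$z_crit, alpha = pt$alpha, n_perm = pt$n_perm,
           seed = pt$seed, n_failed = pt$n_failed),
      p, auto_unbox = TRUE, digits = NA), "threshold.json")
    emit(function(p) data.table::fwrite(
      data.table::data.table(max_abs_z = pt$null_max_abs_z), p, sep = "\t"),
      "null_max_z.tsv")
    pt
  })

  # ---- report ----
  timed("report", {
    raw <- assoc$multinom[assoc$multinom$model == "raw", ]
    flagged <- apply_threshold(raw, thr)
    emit(function(p) data.table::fwrite(assoc$ols, p, sep = "\t"),
         "r2_table.tsv")
    emit(function(p) data.table::fwrite(flagged, p, sep = "\t"),
         "z_matrix.tsv")
    NULL
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("polycomorb")),
    seed = config$seed,
    parameters = list(
      qc = unclass(config$qc), clump = unclass(config$clump),
      thresholds = config$thresholds,
      perm = list(n_perm = config$perm$n_perm, alpha = config$perm$alpha),
      multinom_thresholds = config$multinom_thresholds,
      substances = config$substances),
    timings_sec = as.list(round(timings, 3)),
    checksums = as.list(tools::md5sum(file.path(config$outdir,
                                                sort(unique(outputs)))))
  )
  names(manifest$checksums) <- sort(unique(outputs))
  json <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' Summarize a finished run directory
#'
#' @param results_dir Directory written by [run_all()].
#' @return List with `r2_table` (incremental R-squared of the PRS on GENSUB
#'   per threshold) and `z_matrix` (substance x threshold x level z grid
#'   with significance flags).
#' @export
report_run <- function(results_dir) {
  need <- c("r2_table.tsv", "z_matrix.tsv")
  have <- file.exists(file.path(results_dir, need))
  if (!all(have))
    stop("missing pipeline outputs: ", paste(need[!have], collapse = ", "),
         " (run the association and permutation stages first)")
  list(r2_table = data.table::fread(file.path(results_dir, "r2_table.tsv")),
       z_matrix = data.table::fread(file.path(results_dir, "z_matrix.tsv")))
}
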