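# Plain-text interchange: VCF (GT-only), dosage / summary-statistic /
# phenotype TSVs, PRS profile TSVs.

#' Write genotypes as a minimal VCF
#'
#' Biallelic sites with GT-only FORMAT; missing calls are "./.". Dosages
#' count the ALT allele (`allele_b`), so 0 -> 0/0, 1 -> 0/1, 2 -> 1/1.
#'
#' @param meta Variant metadata (id, chrom, pos, allele_a, allele_b).
#' @param dosage Samples x variants matrix, 0/1/2/NA.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(meta, dosage, path) {
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(meta), nrow(dosage))
  for (v in c(0L, 1L, 2L)) {
    hit <- which(t(dosage) == v)
    gt[hit] <- gt_codes[[as.character(v)]]
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=polycomorb",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(dosage)), collapse = "\t"))
  body <- data.table::data.table(
    CHROM = meta$chrom, POS = meta$pos, ID = meta$id,
    REF = meta$allele_a, ALT = meta$allele_b,
    QUAL = ".", FILTER = "PASS", INFO = ".", FORMAT = "GT")
  body <- cbind(body, data.table::as.data.table(gt))
  writeLines(header, path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a VCF into variant metadata and a dosage matrix
#'
#' Parses biallelic GT calls ("/" or "|" separated); any genotype with a
#' missing allele becomes NA. Dosage counts ALT alleles.
#'
#' @param path VCF path (uncompressed).
#' @return List with `meta` (id, chrom, pos, allele_a = REF,
#'   allele_b = ALT) and `dosage` (samples x variants integer matrix).
#' @export
read_vcf_dosage <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line in ", path)
  tab <- data.table::fread(text = lines[hdr:length(lines)], sep = "\t",
                           header = TRUE)
  data.table::setnames(tab, 1, "CHROM")
  fixed <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT")
  samples <- setdiff(names(tab), fixed)
  gt_field <- function(x) sub(":.*$", "", x)
  count_alt <- function(g) {
    g <- gt_field(g)
    out <- rep(NA_integer_, length(g))
    ok <- grepl("^[0-9]+[/|][0-9]+$", g)
    parts <- strsplit(g[ok], "[/|]")
    out[ok] <- vapply(parts, function(p) sum(as.integer(p) > 0), integer(1))
    out
  }
  dosage <- vapply(samples, function(s) count_alt(tab[[s]]),
                   integer(nrow(tab)))
  dosage <- t(matrix(dosage, nrow = nrow(tab),
                     dimnames = list(tab$ID, samples)))
  list(meta = data.table::data.table(id = tab$ID, chrom = tab$CHROM,
                                     pos = tab$POS, allele_a = tab$REF,
                                     allele_b = tab$ALT),
       dosage = dosage)
}

#' Write / read a dosage matrix TSV
#'
#' Layout: first column `sample_id`, then one integer column per variant id;
#' missing calls are empty fields.
#'
#' @param dosage Samples x variants matrix.
#' @param path File path.
#' @return `path` (write) or the dosage matrix with dimnames (read).
#' @export
write_dosage_tsv <- function(dosage, path) {
  dt <- data.table::data.table(sample_id = rownames(dosage))
  dt <- cbind(dt, data.table::as.data.table(dosage))
  data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  ids <- dt$sample_id
  dt[, sample_id := NULL]
  m <- as.matrix(dt)
  rownames(m) <- ids
  m
}

#' Read GWAS summary statistics
#'
#' Expects columns SNP, CHR, BP, A1, A2, P and either BETA (log odds-ratio)
#' or OR (converted by natural log).
#'
#' @param path TSV path.
#' @return data.table with SNP, CHR, BP, A1, A2, BETA, P.
#' @export
read_sumstats <- function(path) {
  ss <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "P")
  missing_cols <- setdiff(need, names(ss))
  if (length(missing_cols))
    stop("summary statistics missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"BETA" %in% names(ss)) {
    if (!"OR" %in% names(ss)) stop("need a BETA or OR column")
    ss$BETA <- log(ss$OR)
  }
  if (any(ss$P <= 0 | ss$P > 1)) stop("p-values must lie in (0, 1]")
  ss[, c("SNP", "CHR", "BP", "A1", "A2", "BETA", "P"), with = FALSE]
}

#' Write PRS profiles as TSV
#'
#' One row per sample: sample_id plus one score column per threshold.
#'
#' @param profile A `prs_profile` from [build_profiles()].
#' @param path Output path.
#' @export
write_profiles <- function(profile, path) {
  dt <- data.table::data.table(sample_id = rownames(profile$scores))
  dt <- cbind(dt, data.table::as.data.table(profile$scores))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write the phenotype / covariate table
#'
#' @param covariates,involvement Tables from the generator, joined on
#'   sample_id.
#' @param path Output path.
#' @export
write_phenotypes <- function(covariates, involvement, path) {
  dt <- merge(data.table::as.data.table(covariates),
              data.table::as.data.table(involvement), by = "sample_id",
              sort = FALSE)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
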