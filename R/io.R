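# Readers and writers for the interchange formats: summary statistics and
# dosage matrices as TSV, cohorts as CSV, genotypes as VCF 4.2 with a DS
# (dosage) FORMAT field, generative truth as a JSON sidecar.

#' Read / write summary statistics (TSV)
#'
#' Columns: `snp_id`, `chrom`, `pos`, `effect_allele` (`ea`), `other_allele`
#' (`oa`), `weight`, `se`, `pvalue`, `eaf`. Short column names `ea`/`oa`
#' are accepted on input and written on output.
#'
#' @param path file path.
#' @return [read_summary_stats()]: a [summary_stats()] data frame.
#' @export
read_summary_stats <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  nm <- names(x)
  nm[nm == "ea"] <- "effect_allele"
  nm[nm == "oa"] <- "other_allele"
  names(x) <- nm
  summary_stats(x)
}

#' @param stats a [summary_stats()] data frame.
#' @rdname read_summary_stats
#' @export
write_summary_stats <- function(stats, path) {
  out <- data.frame(snp_id = stats$snp_id, chrom = stats$chrom,
                    pos = stats$pos, ea = stats$effect_allele,
                    oa = stats$other_allele, weight = stats$weight,
                    se = stats$se, pvalue = stats$pvalue, eaf = stats$eaf)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a dosage matrix as TSV
#'
#' The TSV carries one row per SNP: `snp_id`, `chrom`, `pos`,
#' `counted_allele`, `other_allele`, then one column per sample.
#'
#' @param path file path.
#' @return [read_dosage_tsv()]: a [genotype_dosage()].
#' @export
read_dosage_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("snp_id", "chrom", "pos", "counted_allele", "other_allele")
  if (!all(meta %in% names(x)))
    stop_grs("dosage TSV lacks column(s): ",
             paste(setdiff(meta, names(x)), collapse = ", "))
  samples <- setdiff(names(x), meta)
  dos <- t(as.matrix(x[, samples, drop = FALSE]))
  colnames(dos) <- x$snp_id
  genotype_dosage(dos, x[, meta])
}

#' @param geno a [genotype_dosage()].
#' @rdname read_dosage_tsv
#' @export
write_dosage_tsv <- function(geno, path) {
  out <- cbind(geno$map[, c("snp_id", "chrom", "pos", "counted_allele",
                            "other_allele")],
               as.data.frame(t(geno$dosage), check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotype dosages as VCF 4.2
#'
#' REF is the other allele and ALT the counted (dosage) allele, so the DS
#' field counts ALT copies. Genotypes are emitted as `./.` with a `DS`
#' value per sample.
#'
#' @param geno a [genotype_dosage()].
#' @param path output path (plain text).
#' @export
write_vcf_dosage <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=grslife",
               '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage of the ALT allele">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno$dosage)),
                     collapse = "\t")), con)
  ds <- format(round(t(geno$dosage), 3), trim = TRUE)
  ds[is.na(t(geno$dosage))] <- "."
  body <- cbind(geno$map$chrom, geno$map$pos, geno$map$snp_id,
                geno$map$other_allele, geno$map$counted_allele,
                ".", "PASS", ".", "DS",
                matrix(paste0("./.:", ds), nrow = nrow(ds)))
  # FORMAT is GT:DS to stay within convention
  body[, 9] <- "GT:DS"
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotype dosages from a VCF with a DS FORMAT field
#'
#' Uses the `vcfR` package when available; expects an uncompressed or
#' gzipped VCF whose FORMAT includes `DS`. The counted allele is ALT.
#'
#' @param path VCF path.
#' @return a [genotype_dosage()].
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_grs("reading VCF requires the 'vcfR' package; use the TSV reader instead")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  map <- data.frame(snp_id = fix$ID, chrom = fix$CHROM,
                    pos = as.integer(fix$POS),
                    counted_allele = fix$ALT, other_allele = fix$REF,
                    stringsAsFactors = FALSE)
  dos <- t(ds)
  colnames(dos) <- map$snp_id
  genotype_dosage(dos, map)
}

#' Read / write a cohort table (CSV)
#'
#' Schema as produced by [simulate_phenotypes()].
#'
#' @param path file path.
#' @return [read_cohort()]: the cohort data frame.
#' @export
read_cohort <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "sex", "entry_age", "exit_age", "event")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop_grs("cohort CSV lacks column(s): ",
             paste(missing_cols, collapse = ", "))
  x
}

#' @param cohort cohort data frame.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the generative truth as a JSON sidecar
#' @param truth a [true_model()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(causal_betas = as.list(truth$causal_betas),
                            true_score = as.list(truth$true_score),
                            covariate_betas = truth$covariate_betas),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
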