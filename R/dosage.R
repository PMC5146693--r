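#' Genotype dosage container
#'
#' A sample-by-SNP matrix of effect-allele dosages in `[0, 2]` (missing
#' allowed) plus a SNP map giving chromosome, 1-based position, the counted
#' (dosage) allele and the other allele.
#'
#' @param dosage numeric matrix, samples in rows, SNPs in columns; row and
#'   column names are used as sample and SNP ids when present.
#' @param map data frame with columns `snp_id`, `chrom`, `pos`,
#'   `counted_allele`, `other_allele`, one row per dosage column.
#' @return object of class `genotype_dosage`.
#' @export
genotype_dosage <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%05d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage))) colnames(dosage) <- map$snp_id
  if (!identical(colnames(dosage), as.character(map$snp_id)))
    stop_grs("dosage column names must match map$snp_id, in order")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop_grs("dosages must lie in [0, 2]")
  if (anyDuplicated(map$snp_id))
    stop_grs("duplicated snp_id in genotype map")
  structure(list(dosage = dosage, map = as.data.frame(map)),
            class = "genotype_dosage")
}

#' @export
print.genotype_dosage <- function(x, ...) {
  cat(sprintf("genotype_dosage: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_dosage <- function(x) dim(x$dosage)

#' Subset a dosage object to a set of SNPs
#' @param geno a [genotype_dosage()] object.
#' @param snp_ids SNP ids to keep, in the requested order.
#' @return a `genotype_dosage` restricted to the SNPs found.
#' @export
subset_snps <- function(geno, snp_ids) {
  keep <- intersect(snp_ids, geno$map$snp_id)
  idx <- match(keep, geno$map$snp_id)
  genotype_dosage(geno$dosage[, idx, drop = FALSE],
                  geno$map[idx, , drop = FALSE])
}

#' Effect-allele frequencies observed in a dosage matrix
#' @param geno a [genotype_dosage()] object.
#' @return numeric vector, column mean dosage / 2 (missing skipped).
#' @export
observed_eaf <- function(geno) {
  colMeans(geno$dosage, na.rm = TRUE) / 2
}
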