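#' Harmonize summary-statistic alleles with cohort dosages
#'
#' Matches SNPs by id and orients the cohort dosages so they count the
#' summary-statistic effect allele. Where the cohort's counted allele
#' equals the stats' other allele, the dosage is reflected (`g <- 2 - g`).
#' Strand-ambiguous SNPs (A/T, C/G) are dropped unless both the reported
#' EAF and the cohort frequency are decisive (`|f - 0.5| > ambiguity_margin`
#' on both sides), in which case frequency concordance determines the
#' orientation. SNPs whose allele pairs do not match as a set, and SNPs
#' present in only one input, are dropped; counts are attached as the
#' `"harmonize_log"` attribute of the returned list.
#'
#' @param stats a [summary_stats()] data frame.
#' @param geno a [genotype_dosage()].
#' @param ambiguity_margin minimum distance of both frequencies from 0.5
#'   for an ambiguous SNP to be kept (default 0.08).
#' @return list with elements `stats`, `geno` (matched, ordered, oriented)
#'   and `log` (a named integer vector of drop reasons).
#' @export
harmonize_alleles <- function(stats, geno, ambiguity_margin = 0.08) {
  shared <- intersect(stats$snp_id, geno$map$snp_id)
  if (length(shared) == 0)
    stop_grs("no overlapping SNP ids between summary statistics and genotypes")
  n_stats_only <- sum(!stats$snp_id %in% shared)
  n_geno_only <- sum(!geno$map$snp_id %in% shared)

  st <- stats[match(shared, stats$snp_id), , drop = FALSE]
  gn <- subset_snps(geno, shared)

  ea <- toupper(st$effect_allele); oa <- toupper(st$other_allele)
  ca <- toupper(gn$map$counted_allele); ga <- toupper(gn$map$other_allele)

  same_orient <- ca == ea & ga == oa
  flip_orient <- ca == oa & ga == ea
  mismatch <- !(same_orient | flip_orient)

  amb <- is_ambiguous_pair(ea, oa) & !mismatch
  keep_amb <- rep(FALSE, length(amb))
  if (any(amb)) {
    f_geno <- observed_eaf(gn)                 # frequency of the counted allele
    f_stats <- st$eaf
    decisive <- abs(f_stats - 0.5) > ambiguity_margin &
      abs(f_geno - 0.5) > ambiguity_margin
    # for an ambiguous pair the labels cannot distinguish strands; use the
    # allele frequencies: counted allele corresponds to the effect allele
    # iff the two frequencies sit on the same side of 0.5
    concordant <- sign(f_stats - 0.5) == sign(f_geno - 0.5)
    keep_amb[amb] <- decisive[amb]
    same_orient[amb] <- decisive[amb] & concordant[amb]
    flip_orient[amb] <- decisive[amb] & !concordant[amb]
  }
  drop <- mismatch | (amb & !keep_amb)
  keep <- which(!drop)
  if (length(keep) == 0)
    stop_grs("no SNPs left after allele harmonization")

  st <- st[keep, , drop = FALSE]
  gn_dos <- gn$dosage[, keep, drop = FALSE]
  gn_map <- gn$map[keep, , drop = FALSE]
  fl <- flip_orient[keep]
  if (any(fl)) {
    gn_dos[, fl] <- 2 - gn_dos[, fl, drop = FALSE]
    tmp <- gn_map$counted_allele[fl]
    gn_map$counted_allele[fl] <- gn_map$other_allele[fl]
    gn_map$other_allele[fl] <- tmp
  }
  rownames(st) <- NULL
  list(stats = summary_stats(st),
       geno = genotype_dosage(gn_dos, gn_map),
       log = c(matched = length(keep), flipped = sum(fl),
               allele_mismatch = sum(mismatch),
               ambiguous_dropped = sum(amb & !keep_amb),
               stats_only = n_stats_only, geno_only = n_geno_only))
}
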