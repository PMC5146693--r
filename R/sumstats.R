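#' Summary-statistics container
#'
#' Validates a data frame of per-SNP GWAS summary statistics: `snp_id`,
#' `chrom`, `pos`, `effect_allele`, `other_allele`, `weight` (log odds per
#' effect-allele copy), `se`, `pvalue`, `eaf`. Extra columns are kept.
#'
#' @param x data frame with the columns above.
#' @return the validated data frame with class `summary_stats` prepended.
#' @export
summary_stats <- function(x) {
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "weight", "se", "pvalue", "eaf")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop_grs("summary statistics lack column(s): ",
             paste(missing_cols, collapse = ", "))
  if (anyDuplicated(x$snp_id))
    stop_grs("duplicated snp_id in summary statistics")
  ok <- is.na(x$pvalue) | (x$pvalue > 0 & x$pvalue <= 1)
  if (!all(ok))
    stop_grs("pvalue outside (0, 1] for ", sum(!ok), " SNP(s)")
  same <- toupper(x$effect_allele) == toupper(x$other_allele)
  if (any(same))
    stop_grs("effect and other allele identical for ", sum(same), " SNP(s)")
  bad_eaf <- !is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1)
  if (any(bad_eaf))
    stop_grs("eaf outside [0, 1] for ", sum(bad_eaf), " SNP(s)")
  x <- as.data.frame(x)
  class(x) <- c("summary_stats", "data.frame")
  x
}

is_ambiguous_pair <- function(a1, a2) {
  p <- paste0(toupper(a1), toupper(a2))
  p %in% c("AT", "TA", "CG", "GC")
}
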