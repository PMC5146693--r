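#' Pairwise linkage-disequilibrium r-squared of two dosage columns
#'
#' Squared Pearson correlation over pairwise-complete samples. Requires at
#' least two complete pairs and non-zero variance in both columns;
#' otherwise returns `NA` with a warning.
#'
#' @param x,y numeric dosage vectors of equal length.
#' @return r-squared in `[0, 1]`, or `NA_real_` when undefined.
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) {
    warning("fewer than 2 pairwise-complete samples: r2 undefined",
            call. = FALSE)
    return(NA_real_)
  }
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) {
    warning("zero dosage variance: r2 undefined", call. = FALSE)
    return(NA_real_)
  }
  r <- cor(x, y)
  min(r * r, 1)
}

#' Greedy LD thinning of summary-statistic SNPs
#'
#' Visits SNPs in ascending p-value (ties broken by ascending chromosome
#' then position) and keeps a SNP unless its r-squared with an
#' already-kept SNP within `window_bp` on the same chromosome exceeds
#' `r2_threshold` — the standard p-value-priority clumping convention. LD
#' is computed from the supplied genotypes; degenerate columns (no
#' variance) are treated as r-squared 0.
#'
#' @param stats a [summary_stats()] data frame (harmonized).
#' @param geno a [genotype_dosage()] containing the stats SNPs.
#' @param r2_threshold threshold in `(0, 1]`; pairs above it are thinned.
#' @param window_bp window width in base pairs (default 1 Mb).
#' @return character vector of kept SNP ids, in visit order.
#' @export
ld_thin <- function(stats, geno, r2_threshold, window_bp = 1e6) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop_grs("r2_threshold must lie in (0, 1]")
  idx_geno <- match(stats$snp_id, geno$map$snp_id)
  if (anyNA(idx_geno))
    stop_grs("genotypes missing for ", sum(is.na(idx_geno)), " stats SNP(s)")
  ord <- order(stats$pvalue, stats$chrom, stats$pos)
  kept <- integer(0)
  for (i in ord) {
    in_window <- kept[stats$chrom[kept] == stats$chrom[i] &
                        abs(stats$pos[kept] - stats$pos[i]) <= window_bp]
    ok <- TRUE
    for (k in in_window) {
      r2 <- suppressWarnings(
        ld_r2(geno$dosage[, idx_geno[i]], geno$dosage[, idx_geno[k]]))
      if (!is.na(r2) && r2 > r2_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  stats$snp_id[kept]
}
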