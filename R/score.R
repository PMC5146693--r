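#' Compute the weighted genomic risk score
#'
#' `raw_i = sum_j w_j g_ij` over the requested SNP subset, using harmonized
#' inputs. Missing dosages are mean-imputed with `2 * eaf_j` (the expected
#' dosage under Hardy-Weinberg), keeping scores comparable across subjects
#' with different missingness. SNPs with missing weights are skipped and
#' reduce the reported coverage.
#'
#' @param stats a [summary_stats()] data frame (harmonized).
#' @param geno a [genotype_dosage()] (harmonized).
#' @param snp_subset SNP ids to use; default all stats SNPs.
#' @return object of class `score_vector`: `sample_ids`, `raw`,
#'   `standardized` (filled by [standardize_score()]), `n_snps_used`,
#'   `coverage`.
#' @export
compute_grs <- function(stats, geno, snp_subset = NULL) {
  if (is.null(snp_subset)) snp_subset <- stats$snp_id
  if (length(snp_subset) == 0)
    stop_grs("empty SNP subset: cannot compute a score")
  requested <- length(snp_subset)
  use <- intersect(snp_subset, intersect(stats$snp_id, geno$map$snp_id))
  si <- match(use, stats$snp_id)
  usable <- !is.na(stats$weight[si])
  use <- use[usable]; si <- si[usable]
  if (length(use) == 0)
    stop_grs("no usable SNPs in subset (all missing from inputs or flagged)")
  gi <- match(use, geno$map$snp_id)
  w <- stats$weight[si]
  g <- geno$dosage[, gi, drop = FALSE]
  if (anyNA(g)) {
    imp <- 2 * stats$eaf[si]
    na_idx <- which(is.na(g), arr.ind = TRUE)
    g[na_idx] <- imp[na_idx[, 2]]
  }
  raw <- drop(g %*% w)
  structure(list(sample_ids = rownames(geno$dosage), raw = raw,
                 standardized = NULL, n_snps_used = length(use),
                 coverage = length(use) / requested),
            class = "score_vector")
}

#' Standardize a score to mean 0, SD 1
#'
#' Standardization is always recomputed from the raw score (sample SD,
#' denominator `n - 1`), so the operation is idempotent.
#'
#' @param score a `score_vector` from [compute_grs()].
#' @return the score with `standardized` filled in.
#' @export
standardize_score <- function(score) {
  s <- sd(score$raw)
  if (!is.finite(s) || s == 0)
    stop_grs("cannot standardize: raw score is constant (SD = 0)")
  score$standardized <- (score$raw - mean(score$raw)) / s
  score
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector: %d samples, %d SNPs used (coverage %.1f%%)\n",
              length(x$raw), x$n_snps_used, 100 * x$coverage))
  invisible(x)
}

#' Write scores as CSV (sample_id, raw, standardized)
#' @param score a `score_vector`.
#' @param path output path.
#' @export
write_scores <- function(score, path) {
  write.csv(data.frame(sample_id = score$sample_ids, raw = score$raw,
                       standardized = score$standardized %||% NA_real_),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select the LD r-squared threshold by AUC
#'
#' For each threshold in the grid: thin the SNPs ([ld_thin()]), compute and
#' standardize the score, then evaluate it against a binary outcome with a
#' per-SD logistic odds ratio and the AUC. Returns the threshold with the
#' highest AUC; ties are broken toward the larger threshold (fewer SNPs
#' removed).
#'
#' @param stats,geno harmonized summary statistics and dosages.
#' @param outcome binary vector (0/1) aligned to the genotype samples.
#' @param grid thresholds to evaluate (default
#'   `c(1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.3, 0.1)`).
#' @param window_bp thinning window (default 1 Mb).
#' @return object of class `thinning_result`: `r2_threshold` (selected),
#'   `kept_snp_ids` at the selected threshold, and `table` with one row per
#'   threshold (n_kept, AUC with CI, per-SD OR with CI).
#' @export
select_r2_threshold <- function(stats, geno, outcome,
                                grid = c(1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.3, 0.1),
                                window_bp = 1e6) {
  if (length(grid) == 0) stop_grs("threshold grid is empty")
  outcome <- as.integer(outcome)
  if (length(unique(outcome[!is.na(outcome)])) < 2)
    stop_grs("outcome is degenerate: both classes required")
  rows <- vector("list", length(grid))
  kept_sets <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    kept <- ld_thin(stats, geno, grid[i], window_bp)
    sc <- standardize_score(compute_grs(stats, geno, kept))
    a <- auc_binary(outcome, sc$standardized)
    orr <- logistic_per_sd(outcome, sc$standardized)
    rows[[i]] <- data.frame(r2_threshold = grid[i], n_kept = length(kept),
                            auc = a$auc, auc_lo = a$ci[1], auc_hi = a$ci[2],
                            or_per_sd = orr$or, or_lo = orr$ci[1],
                            or_hi = orr$ci[2])
    kept_sets[[i]] <- kept
  }
  tab <- do.call(rbind, rows)
  # max AUC; ties toward the larger threshold
  best <- which(tab$auc == max(tab$auc))
  best <- best[which.max(tab$r2_threshold[best])]
  structure(list(r2_threshold = grid[best],
                 kept_snp_ids = kept_sets[[best]],
                 table = tab),
            class = "thinning_result")
}

#' @export
print.thinning_result <- function(x, ...) {
  cat(sprintf("thinning_result: selected r2 threshold %.2f (%d SNPs kept)\n",
              x$r2_threshold, length(x$kept_snp_ids)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
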