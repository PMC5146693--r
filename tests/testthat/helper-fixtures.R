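# shared fixture builders -- everything is generated in code

# minimal cohort table from parallel vectors
make_cohort <- function(entry, exit, event, sex = NULL, ...) {
  n <- length(entry)
  out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                    sex = sex %||% rep("male", n),
                    entry_age = entry, exit_age = exit, event = event,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small genotype fixture with explicit alleles/positions
make_geno <- function(dosage, chrom = NULL, pos = NULL,
                      counted = NULL, other = NULL) {
  m <- ncol(dosage)
  map <- data.frame(snp_id = colnames(dosage) %||% sprintf("snp%d", 1:m),
                    chrom = chrom %||% rep(1L, m),
                    pos = pos %||% (seq_len(m) * 1000L),
                    counted_allele = counted %||% rep("A", m),
                    other_allele = other %||% rep("G", m),
                    stringsAsFactors = FALSE)
  colnames(dosage) <- map$snp_id
  genotype_dosage(dosage, map)
}

make_stats <- function(snp_id, weight, pvalue = NULL, eaf = NULL,
                       chrom = NULL, pos = NULL, ea = NULL, oa = NULL) {
  m <- length(snp_id)
  summary_stats(data.frame(
    snp_id = snp_id, chrom = chrom %||% rep(1L, m),
    pos = pos %||% (seq_len(m) * 1000L),
    effect_allele = ea %||% rep("A", m), other_allele = oa %||% rep("G", m),
    weight = weight, se = rep(0.01, m),
    pvalue = pvalue %||% rep(0.5, m), eaf = eaf %||% rep(0.3, m),
    stringsAsFactors = FALSE))
}

# brute-force O(n^2) truncated concordance oracle
cindex_oracle <- function(time, status, score, horizon = Inf) {
  conc <- 0; pairs <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (status[i] != 1 || time[i] > horizon) next
    for (j in seq_len(n)) {
      if (j == i || time[j] <= time[i]) next
      pairs <- pairs + 1
      conc <- conc + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
    }
  }
  list(c = conc / pairs, n_pairs = pairs)
}

# exhaustive greedy thinning oracle for tiny SNP sets: visit in p-value
# order (ties by chrom, pos), keep unless r2 with a kept in-window SNP
# exceeds the threshold; r2 from plain cor()^2
thin_oracle <- function(stats, dosage, threshold, window_bp = 1e6) {
  ord <- order(stats$pvalue, stats$chrom, stats$pos)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (stats$chrom[k] == stats$chrom[i] &&
          abs(stats$pos[k] - stats$pos[i]) <= window_bp) {
        r2 <- suppressWarnings(cor(dosage[, i], dosage[, k],
                                   use = "pairwise.complete.obs")^2)
        if (!is.na(r2) && r2 > threshold) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- c(kept, i)
  }
  stats$snp_id[kept]
}
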