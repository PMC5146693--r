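# Synthetic data generator: LD-blocked genotypes, GWAS-style summary
# statistics, and Weibull proportional-hazards survival records with
# competing non-CHD mortality. Everything is driven by a sim_config and a
# single integer seed; each generator derives its own sub-seed so the
# pieces are individually reproducible.

NON_AMBIGUOUS_PAIRS <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"),
                            c("C", "A"), c("G", "A"), c("C", "T"), c("G", "T"))
AMBIGUOUS_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

block_index <- function(n_snps, block_size) {
  rep(seq_len(ceiling(n_snps / block_size)), each = block_size)[seq_len(n_snps)]
}

# one haplotype matrix: latent AR(1) Gaussian per block, thresholded so the
# allele indicator has probability maf
simulate_haplotype <- function(n, thresholds, blocks, rho) {
  m <- length(thresholds)
  z <- matrix(rnorm(n * m), n, m)
  if (m > 1 && rho > 0) {
    w <- sqrt(1 - rho^2)
    for (j in 2:m) {
      if (blocks[j] == blocks[j - 1])
        z[, j] <- rho * z[, j - 1] + w * z[, j]
    }
  }
  (z > matrix(thresholds, n, m, byrow = TRUE)) + 0L
}

#' Simulate LD-blocked genotype dosages
#'
#' Two independent haplotypes per subject, each generated from a block-wise
#' AR(1) latent Gaussian thresholded at `qnorm(1 - maf)` and summed, so
#' dosages are exact `{0, 1, 2}` counts, adjacent SNPs within a block are
#' correlated (increasingly so with `rho`) and SNPs in different blocks are
#' independent. Blocks are laid out along 22 chromosomes with 5 kb spacing
#' within a block and 10 Mb between blocks on the same chromosome.
#'
#' @param config a [sim_config()].
#' @return a [genotype_dosage()] with per-SNP allele labels.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  n <- config$n_samples; m <- config$n_snps
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  thr <- qnorm(1 - maf)
  blocks <- block_index(m, config$block_size)

  dos <- simulate_haplotype(n, thr, blocks, config$rho) +
    simulate_haplotype(n, thr, blocks, config$rho)
  storage.mode(dos) <- "double"

  n_blocks <- max(blocks)
  chrom_of_block <- ((seq_len(n_blocks) - 1L) %% 22L) + 1L
  block_rank <- stats::ave(seq_len(n_blocks), chrom_of_block,
                           FUN = seq_along)
  within <- stats::ave(seq_len(m), blocks, FUN = seq_along)
  pos <- 1e6 + (block_rank[blocks] - 1L) * 1e7 + (within - 1L) * 5000

  amb <- runif(m) < config$prop_ambiguous
  pair_idx <- sample.int(length(NON_AMBIGUOUS_PAIRS), m, replace = TRUE)
  amb_idx <- sample.int(length(AMBIGUOUS_PAIRS), m, replace = TRUE)
  counted <- ifelse(amb, vapply(AMBIGUOUS_PAIRS[amb_idx], `[`, "", 1),
                    vapply(NON_AMBIGUOUS_PAIRS[pair_idx], `[`, "", 1))
  other <- ifelse(amb, vapply(AMBIGUOUS_PAIRS[amb_idx], `[`, "", 2),
                  vapply(NON_AMBIGUOUS_PAIRS[pair_idx], `[`, "", 2))

  map <- data.frame(snp_id = sprintf("rs%06d", seq_len(m)),
                    chrom = chrom_of_block[blocks], pos = pos,
                    counted_allele = counted, other_allele = other,
                    maf = maf, block = blocks,
                    stringsAsFactors = FALSE)
  colnames(dos) <- map$snp_id
  rownames(dos) <- sprintf("S%05d", seq_len(n))
  genotype_dosage(dos, map)
}

#' Generative truth for a simulated cohort
#'
#' Draws the causal architecture: a random `prop_causal` fraction of SNPs
#' receives a true per-allele log-odds effect `N(0, causal_beta_sd^2)`, the
#' rest are exactly zero; the true score is the dosage matrix times these
#' effects. Covariate log hazard ratios are carried along from the config.
#'
#' @param geno a [genotype_dosage()] from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return object of class `true_model` with `causal_betas`, `true_score`,
#'   and `covariate_betas`.
#' @export
true_model <- function(geno, config) {
  set.seed(config$seed + 11L)
  m <- ncol(geno$dosage)
  n_causal <- max(1L, round(config$prop_causal * m))
  causal <- sort(sample.int(m, n_causal))
  beta <- numeric(m)
  beta[causal] <- rnorm(n_causal, 0, config$causal_beta_sd)
  score <- drop(geno$dosage %*% beta)
  structure(list(causal_betas = setNames(beta, geno$map$snp_id),
                 true_score = setNames(score, rownames(geno$dosage)),
                 covariate_betas = config$covariate_log_hr),
            class = "true_model")
}

#' Simulate GWAS summary statistics
#'
#' Per-SNP reported weights are the true log-odds effects plus Gaussian
#' noise with standard error `1/sqrt(2 p (1-p) gwas_n)` where `p` is the
#' observed effect-allele frequency; p-values come from the Wald z
#' statistic. A fraction `prop_flipped` of rows is reported on the opposite
#' allele (weight negated, EAF complemented, allele labels swapped), which
#' downstream allele harmonization must undo. Monomorphic SNPs get a
#' missing weight and a `flag`.
#'
#' @param geno a [genotype_dosage()].
#' @param truth a [true_model()].
#' @param config the [sim_config()].
#' @return a summary-statistics data frame (see [summary_stats()]).
#' @export
simulate_summary_stats <- function(geno, truth, config) {
  if (!identical(names(truth$causal_betas), geno$map$snp_id))
    stop_grs("truth and genotype SNP sets do not match")
  set.seed(config$seed + 2L)
  p <- observed_eaf(geno)
  mono <- p <= 0 | p >= 1
  se <- ifelse(mono, NA_real_, 1 / sqrt(2 * p * (1 - p) * config$gwas_n))
  beta <- truth$causal_betas
  noise <- if (is.finite(config$gwas_n)) rnorm(length(p), 0, ifelse(mono, 0, se)) else 0
  w <- ifelse(mono, NA_real_, beta + noise)
  z <- ifelse(is.na(w) | se == 0 | is.na(se),
              ifelse(!is.na(w) & w != 0, Inf, 0), w / se)
  pval <- 2 * pnorm(-abs(z))
  pval[is.na(w)] <- NA_real_
  pval <- pmax(pval, .Machine$double.xmin)  # p in (0, 1]

  stats <- data.frame(snp_id = geno$map$snp_id, chrom = geno$map$chrom,
                      pos = geno$map$pos,
                      effect_allele = geno$map$counted_allele,
                      other_allele = geno$map$other_allele,
                      weight = w, se = se, pvalue = pval, eaf = p,
                      flag = ifelse(mono, "monomorphic", ""),
                      stringsAsFactors = FALSE)

  flip <- runif(nrow(stats)) < config$prop_flipped
  flip[mono] <- FALSE
  ea <- stats$effect_allele
  stats$effect_allele[flip] <- stats$other_allele[flip]
  stats$other_allele[flip] <- ea[flip]
  stats$weight[flip] <- -stats$weight[flip]
  stats$eaf[flip] <- 1 - stats$eaf[flip]
  summary_stats(stats)
}

rweibull_cond <- function(entry, shape, scale, lp) {
  # event age from a Weibull PH model conditional on being event-free at
  # `entry` (left truncation): inverse of the conditional survival function
  u <- runif(length(entry))
  scale * ((entry / scale)^shape - log(u) * exp(-lp))^(1 / shape)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Simulate a survival cohort from genotypes and the generative truth
#'
#' Baseline covariates are drawn from the configured distributions; entry
#' ages from a truncated normal so the cohort always has delayed entry on
#' the age scale. CHD event ages follow a Weibull proportional-hazards
#' model on attained age whose linear predictor is
#' `log(target_hr_per_sd) * standardized true score + covariate terms`;
#' competing (non-CHD) death ages are drawn independently from a second
#' Weibull with its own linear predictor. The observed record is the
#' earliest of CHD, competing death and administrative censoring at
#' `entry + admin_censor_years`. Family history is a Bernoulli indicator
#' whose logit is linear in the standardized true score; a small
#' age/score-dependent fraction carries prevalent CVD for the exclusion
#' filter to remove.
#'
#' @param geno a [genotype_dosage()].
#' @param truth a [true_model()].
#' @param config the [sim_config()].
#' @return a cohort data frame with columns `sample_id`, `sex`, `entry_age`,
#'   `exit_age`, `event` (`"chd"`, `"death_other"`, `"censored"`),
#'   `smoking`, `sbp`, `tc`, `hdl`, `diabetes`, `lipid_treatment`,
#'   `bp_treatment`, `family_history`, `prevalent_cvd`, `cohort`, `region`.
#' @export
simulate_phenotypes <- function(geno, truth, config) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  n <- nrow(geno$dosage)
  bc <- config$baseline_covariates

  sex <- ifelse(runif(n) < 0.5, "male", "female")
  entry <- rtruncnorm1(n, bc$age_mean, bc$age_sd,
                       bc$age_range[1], bc$age_range[2])
  smoking <- rbinom(n, 1, bc$smoking_prev)
  diabetes <- rbinom(n, 1, bc$diabetes_prev)
  sbp <- pmax(rnorm(n, bc$sbp_mean, bc$sbp_sd), 70)
  tc <- pmax(rnorm(n, bc$tc_mean, bc$tc_sd), 1.5)
  hdl <- pmax(rnorm(n, bc$hdl_mean, bc$hdl_sd), 0.3)
  lipid_trt <- rbinom(n, 1, bc$lipid_trt_prev)
  bp_trt <- rbinom(n, 1, bc$bp_trt_prev)

  s <- as.vector(scale(truth$true_score))
  if (!is.finite(sd(truth$true_score)) || sd(truth$true_score) == 0)
    s <- rep(0, n)
  cb <- truth$covariate_betas
  lp_chd <- log(config$target_hr_per_sd) * s +
    cb$smoking * smoking + cb$diabetes * diabetes +
    cb$male * (sex == "male") +
    cb$sbp_per_sd * (sbp - bc$sbp_mean) / bc$sbp_sd +
    cb$tc_per_sd * (tc - bc$tc_mean) / bc$tc_sd +
    cb$hdl_per_sd * (hdl - bc$hdl_mean) / bc$hdl_sd
  comp <- config$competing_log_hr
  lp_death <- comp$smoking * smoking + comp$male * (sex == "male")

  t_chd <- rweibull_cond(entry, config$weibull_shape, config$weibull_scale,
                         lp_chd)
  t_death <- rweibull_cond(entry, config$competing_shape,
                           config$competing_scale, lp_death)
  t_admin <- entry + config$admin_censor_years
  exit <- pmin(t_chd, t_death, t_admin)
  event <- ifelse(exit == t_chd, "chd",
                  ifelse(exit == t_death, "death_other", "censored"))

  fh <- rbinom(n, 1, plogis(qlogis(config$fh_base_prev) + config$fh_coef * s))
  prevalent <- rbinom(n, 1, plogis(-3.5 + 0.035 * (entry - bc$age_mean) +
                                     0.25 * s))

  data.frame(sample_id = rownames(geno$dosage), sex = sex,
             entry_age = entry, exit_age = exit, event = event,
             smoking = smoking, sbp = sbp, tc = tc, hdl = hdl,
             diabetes = diabetes, lipid_treatment = lipid_trt,
             bp_treatment = bp_trt, family_history = fh,
             prevalent_cvd = prevalent,
             cohort = sample(c("c92", "c97", "c02"), n, replace = TRUE),
             region = sample(c("east", "west"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Apply prospective-cohort exclusion and censoring rules
#'
#' Removes subjects with prevalent cardiovascular disease at baseline and
#' subjects younger than `min_baseline_age` at entry, and truncates
#' follow-up at attained age `censor_age`: exits beyond it are set to the
#' censoring age and their events recoded as censored. Records whose
#' truncated exit would not exceed their entry (entry at or above the
#' censoring age) are dropped with a warning. The operation is idempotent
#' and leaves its input unchanged.
#'
#' @param cohort cohort data frame (see [simulate_phenotypes()]).
#' @param min_baseline_age minimum baseline age in years (default 30).
#' @param censor_age attained-age censoring limit in years (default 75).
#' @return the filtered cohort; exclusion counts are attached as the
#'   `"filter_log"` attribute.
#' @export
apply_cohort_filters <- function(cohort, min_baseline_age = 30,
                                 censor_age = 75) {
  if (censor_age <= min_baseline_age)
    stop_grs("censor_age must exceed min_baseline_age")
  out <- cohort
  n0 <- nrow(out)
  if (n0 == 0) {
    attr(out, "filter_log") <- list(n_in = 0L, prevalent = 0L, young = 0L,
                                    invalid = 0L, truncated = 0L, n_out = 0L)
    return(out)
  }
  prev <- if ("prevalent_cvd" %in% names(out)) out$prevalent_cvd == 1 else
    rep(FALSE, n0)
  young <- out$entry_age < min_baseline_age
  out <- out[!prev & !young, , drop = FALSE]

  over <- out$exit_age > censor_age
  out$exit_age[over] <- censor_age
  out$event[over] <- "censored"
  bad <- out$exit_age <= out$entry_age
  if (any(bad))
    warning(sum(bad), " record(s) dropped: no follow-up left after ",
            "censoring at age ", censor_age, call. = FALSE)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- list(n_in = n0, prevalent = sum(prev),
                                  young = sum(young & !prev),
                                  invalid = sum(bad),
                                  truncated = sum(over & !bad),
                                  n_out = nrow(out))
  out
}
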