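#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator: genotype LD structure, GWAS
#' summary-statistic noise, the proportional-hazards survival model and the
#' baseline covariate distributions. Defaults emulate a Finnish-style
#' population cohort: mean baseline age 45.97 (SD 12.7) years, systolic
#' blood pressure 134.93 (19.7) mmHg, total cholesterol 5.58 (1.11) mmol/L,
#' HDL 1.45 (0.38) mmol/L, 26% current smokers, 5% prevalent diabetes,
#' roughly 6% incident CHD over ~15 years of follow-up censored at attained
#' age 75, and a hazard ratio of 1.74 per SD of the true genetic score.
#'
#' @param n_samples number of subjects.
#' @param n_snps number of SNPs.
#' @param block_size SNPs per LD block; the last block may be short.
#' @param rho within-block AR(1) latent-Gaussian correlation, in `[0, 1)`.
#' @param maf_range range of effect-allele frequencies, each in `(0, 0.5]`.
#' @param prop_causal fraction of SNPs with non-zero true effect, in `(0, 1]`.
#' @param causal_beta_sd SD of the true per-allele log-odds effects.
#' @param prop_flipped fraction of summary-stat rows reported on the
#'   opposite allele (weight negated, EAF complemented) to exercise allele
#'   harmonization.
#' @param prop_ambiguous fraction of SNPs given strand-ambiguous (A/T or
#'   C/G) allele pairs.
#' @param target_hr_per_sd hazard ratio of incident CHD per SD of the true
#'   score; must be positive.
#' @param gwas_n effective sample size behind the summary statistics; the
#'   per-SNP weight noise SD is `1/sqrt(2 p (1-p) gwas_n)`. `Inf` gives
#'   noise-free weights.
#' @param covariate_log_hr named list of log hazard ratios for the CHD
#'   cause: `smoking`, `diabetes`, `male` (indicators) and `sbp_per_sd`,
#'   `tc_per_sd`, `hdl_per_sd` (per SD of the covariate).
#' @param competing_log_hr named list of log hazard ratios for non-CHD
#'   mortality (`smoking`, `male`).
#' @param fh_coef log-odds of self-reported family history per SD of the
#'   true score.
#' @param fh_base_prev baseline family-history prevalence.
#' @param baseline_covariates named list of covariate means/SDs and
#'   prevalences (see defaults).
#' @param weibull_shape,weibull_scale Weibull baseline hazard of CHD on the
#'   attained-age scale (years).
#' @param competing_shape,competing_scale Weibull hazard of non-CHD death.
#' @param admin_censor_years administrative censoring after entry, years.
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 5000,
                       n_snps = 2000,
                       block_size = 20,
                       rho = 0.8,
                       maf_range = c(0.05, 0.5),
                       prop_causal = 0.2,
                       causal_beta_sd = 0.05,
                       prop_flipped = 0.3,
                       prop_ambiguous = 0.05,
                       target_hr_per_sd = 1.74,
                       gwas_n = 185000,
                       covariate_log_hr = list(smoking = 0.55, diabetes = 0.60,
                                               male = 0.70, sbp_per_sd = 0.25,
                                               tc_per_sd = 0.30, hdl_per_sd = -0.35),
                       competing_log_hr = list(smoking = 0.40, male = 0.60),
                       fh_coef = 0.3,
                       fh_base_prev = 0.15,
                       baseline_covariates = list(
                         age_mean = 45.97, age_sd = 12.7, age_range = c(25, 74),
                         sbp_mean = 134.93, sbp_sd = 19.7,
                         tc_mean = 5.58, tc_sd = 1.11,
                         hdl_mean = 1.45, hdl_sd = 0.38,
                         smoking_prev = 0.26, diabetes_prev = 0.05,
                         lipid_trt_prev = 0.03, bp_trt_prev = 0.11),
                       weibull_shape = 5, weibull_scale = 115,
                       competing_shape = 6, competing_scale = 80,
                       admin_censor_years = 15,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              block_size = as.integer(block_size), rho = rho,
              maf_range = maf_range, prop_causal = prop_causal,
              causal_beta_sd = causal_beta_sd, prop_flipped = prop_flipped,
              prop_ambiguous = prop_ambiguous,
              target_hr_per_sd = target_hr_per_sd, gwas_n = gwas_n,
              covariate_log_hr = covariate_log_hr,
              competing_log_hr = competing_log_hr,
              fh_coef = fh_coef, fh_base_prev = fh_base_prev,
              baseline_covariates = baseline_covariates,
              weibull_shape = weibull_shape, weibull_scale = weibull_scale,
              competing_shape = competing_shape,
              competing_scale = competing_scale,
              admin_censor_years = admin_censor_years,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 2 || cfg$n_snps < 1 || cfg$block_size < 1)
    stop_grs("invalid configuration dimensions: n_samples, n_snps and block_size must be positive")
  if (cfg$rho < 0 || cfg$rho >= 1)
    stop_grs("rho must lie in [0, 1)")
  if (any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5) ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop_grs("maf_range must be increasing with values in (0, 0.5]")
  if (cfg$prop_causal <= 0 || cfg$prop_causal > 1)
    stop_grs("prop_causal must lie in (0, 1]")
  if (cfg$target_hr_per_sd <= 0)
    stop_grs("target_hr_per_sd must be positive")
  if (cfg$weibull_shape <= 0 || cfg$weibull_scale <= 0 ||
      cfg$competing_shape <= 0 || cfg$competing_scale <= 0)
    stop_grs("Weibull shape and scale parameters must all be positive")
  if (cfg$admin_censor_years <= 0)
    stop_grs("admin_censor_years must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d subjects, %d SNPs in blocks of %d (rho = %.2f)\n",
              x$n_samples, x$n_snps, x$block_size, x$rho))
  cat(sprintf("  target HR per SD of true score: %.2f; GWAS n = %s\n",
              x$target_hr_per_sd, format(x$gwas_n)))
  cat(sprintf("  CHD baseline Weibull(%.1f, %.1f); competing Weibull(%.1f, %.1f)\n",
              x$weibull_shape, x$weibull_scale, x$competing_shape,
              x$competing_scale))
  cat(sprintf("  admin censoring %.0f y after entry; seed %d\n",
              x$admin_censor_years, x$seed))
  invisible(x)
}
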