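# Coefficient-table engine for published 10-year clinical risk equations
# of the Cox form  risk = 1 - S0 ^ exp(LP - LPbar).
#
# A score config is a coefficient table plus a per-stratum manifest. Each
# coefficient row contributes
#   coefficient * t1(scale1 * x1) [* t2(scale2 * x2)] [* (condition == value)]
# which covers log transforms, unit conversions (e.g. mmol/L -> mg/dL),
# product (interaction) terms such as ln(age) x smoker, squared terms, and
# treated/untreated blood-pressure splits.

#' Load a clinical risk score configuration
#'
#' Reads a TSV coefficient table and its JSON manifest. Two configurations
#' ship with the package: `"frs"` (Framingham-style general CVD equation,
#' sex-specific, log-transformed covariates) and `"accaha13"`
#' (pooled-cohort-equation style, sex-specific, white-stratum coefficients
#' — cohorts without race information use this stratum).
#'
#' @param name `"frs"`, `"accaha13"`, or a path prefix so that
#'   `<prefix>.tsv` and `<prefix>.json` exist.
#' @return object of class `clinical_score_config`.
#' @export
load_clinical_score <- function(name) {
  if (name %in% c("frs", "accaha13")) {
    prefix <- file.path(system.file("extdata", "clinical_scores",
                                    package = "grslife"), name)
  } else prefix <- name
  tsv <- paste0(prefix, ".tsv"); js <- paste0(prefix, ".json")
  if (!file.exists(tsv) || !file.exists(js))
    stop_grs("clinical score files not found: ", tsv, " / ", js)
  coefs <- read.delim(tsv, stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(js, simplifyVector = TRUE)
  clinical_score_config(coefs, manifest)
}

#' Construct a clinical score configuration
#'
#' @param coefs data frame with columns `stratum`, `covariate`, `transform`
#'   (`identity` or `log`), `scale` (unit conversion applied before the
#'   transform), optional `covariate2`/`transform2`/`scale2` for product
#'   terms, optional `condition`/`condition_value` restricting a term to
#'   subjects with that covariate value, and `coefficient`.
#' @param manifest list with `name`, `version`, and `strata`: a data frame
#'   or named list giving per-stratum `s0` (baseline 10-year survival, in
#'   `(0,1)`) and `lp_mean` (the population mean linear predictor).
#' @return object of class `clinical_score_config`.
#' @export
clinical_score_config <- function(coefs, manifest) {
  needed <- c("stratum", "covariate", "transform", "coefficient")
  if (!all(needed %in% names(coefs)))
    stop_grs("coefficient table lacks column(s): ",
             paste(setdiff(needed, names(coefs)), collapse = ", "))
  if (!all(coefs$transform %in% c("identity", "log")))
    stop_grs("transform must be 'identity' or 'log'")
  strata <- as.data.frame(manifest$strata)
  if (!all(c("stratum", "s0", "lp_mean") %in% names(strata)))
    stop_grs("manifest strata need 'stratum', 's0', 'lp_mean'")
  if (any(strata$s0 <= 0 | strata$s0 >= 1))
    stop_grs("baseline survival s0 must lie in (0, 1)")
  if (!all(coefs$stratum %in% strata$stratum))
    stop_grs("coefficient rows reference unknown strata")
  structure(list(name = manifest$name %||% "clinical_score",
                 version = manifest$version %||% "unversioned",
                 coefs = coefs, strata = strata),
            class = "clinical_score_config")
}

val_or <- function(x, default) {
  if (is.null(x) || length(x) == 0 || is.na(x) ||
      (is.character(x) && !nzchar(x))) default else x
}

apply_transform <- function(x, transform, scale) {
  x <- x * scale
  if (transform == "log") {
    if (any(x[!is.na(x)] <= 0))
      stop_grs("log transform applied to non-positive covariate values")
    log(x)
  } else x
}

#' Per-sample linear predictor of a clinical risk score
#'
#' Sums the configured coefficient terms within each subject's stratum.
#' Subjects with any missing required covariate get `NA` and are counted in
#' the `"n_missing"` attribute (downstream reclassification excludes them).
#'
#' @param cohort cohort data frame; covariate names in the coefficient
#'   table must exist as columns, and `sex` identifies the stratum.
#' @param config a `clinical_score_config`.
#' @return numeric vector of linear predictors with attribute `n_missing`.
#' @export
linear_predictor <- function(cohort, config) {
  covs <- c(config$coefs$covariate,
            if ("covariate2" %in% names(config$coefs)) config$coefs$covariate2,
            if ("condition" %in% names(config$coefs)) config$coefs$condition)
  covs <- unique(covs[!is.na(covs) & nzchar(covs)])
  miss_cols <- setdiff(covs, names(cohort))
  if (length(miss_cols))
    stop_grs("cohort lacks covariate(s): ", paste(miss_cols, collapse = ", "))
  lp <- numeric(nrow(cohort))
  incomplete <- rep(FALSE, nrow(cohort))
  for (s in unique(config$coefs$stratum)) {
    in_s <- cohort$sex == s
    if (!any(in_s)) next
    rows <- config$coefs[config$coefs$stratum == s, , drop = FALSE]
    lps <- numeric(sum(in_s))
    for (r in seq_len(nrow(rows))) {
      rw <- rows[r, ]
      term <- apply_transform(cohort[[rw$covariate]][in_s], rw$transform,
                              val_or(rw$scale, 1))
      cov2 <- val_or(rw$covariate2, NA)
      if (!is.na(cov2))
        term <- term * apply_transform(cohort[[cov2]][in_s],
                                       val_or(rw$transform2, "identity"),
                                       val_or(rw$scale2, 1))
      cond <- val_or(rw$condition, NA)
      if (!is.na(cond))
        term <- term * (cohort[[cond]][in_s] == rw$condition_value)
      lps <- lps + rw$coefficient * term
    }
    lp[in_s] <- lps
    incomplete[in_s] <- incomplete[in_s] | is.na(lps)
  }
  lp[incomplete] <- NA_real_
  unknown <- !cohort$sex %in% config$coefs$stratum
  lp[unknown] <- NA_real_
  attr(lp, "n_missing") <- sum(incomplete | unknown)
  lp
}

#' 10-year risk from a published Cox-form equation
#'
#' `risk = 1 - S0 ^ exp(LP - LPbar)` with the per-stratum baseline 10-year
#' survival `S0` and mean linear predictor `LPbar` from the manifest.
#'
#' @param lp linear predictors from [linear_predictor()].
#' @param cohort the cohort (for the stratum column `sex`).
#' @param config a `clinical_score_config`.
#' @return data frame `sample_id`, `risk` in `[0, 1]`, `linear_predictor`.
#' @export
risk10_from_equation <- function(lp, cohort, config) {
  s0 <- setNames(config$strata$s0, config$strata$stratum)
  lpbar <- setNames(config$strata$lp_mean, config$strata$stratum)
  st <- as.character(cohort$sex)
  risk <- 1 - s0[st]^exp(lp - lpbar[st])
  data.frame(sample_id = cohort$sample_id, risk = unname(risk),
             linear_predictor = as.numeric(lp))
}

#' Compute a clinical 10-year risk for a cohort
#'
#' Convenience wrapper: [linear_predictor()] then [risk10_from_equation()].
#'
#' @inheritParams linear_predictor
#' @return as [risk10_from_equation()], with attribute `n_missing`.
#' @export
clinical_risk10 <- function(cohort, config) {
  lp <- linear_predictor(cohort, config)
  out <- risk10_from_equation(lp, cohort, config)
  attr(out, "n_missing") <- attr(lp, "n_missing")
  out
}
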