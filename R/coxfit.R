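# Age-timescale Cox machinery: sex-stratified fits with delayed entry
# (left truncation), Breslow baseline cumulative hazard per stratum,
# model-based 10-year risks, and GRS x risk-factor interaction tests.
# Partial-likelihood maximization is delegated to survival::coxph (Efron
# tie correction); risk sets use (entry, exit] intervals.

#' Fit a cause-specific, sex-stratified Cox model on the age scale
#'
#' Builds `Surv(entry_age, exit_age, event == cause)` so the time axis is
#' attained age with delayed entry at baseline, stratifies the baseline
#' hazard by `strata` (default sex), and treats events of other causes as
#' censoring (the cause-specific convention). Ties are handled with the
#' Efron correction.
#'
#' @param cohort cohort data frame (see [simulate_phenotypes()]).
#' @param covariates character vector of column names (factors allowed).
#' @param strata stratification column, default `"sex"`; `NULL` for none.
#' @param cause event label counted as the event (default `"chd"`).
#' @param iter_max maximum Newton iterations (default 100).
#' @return object of class `cox_fit`: `coefficients`, `vcov`, `hr` table
#'   (HR, 95% CI, z, p), per-stratum Breslow `baseline` cumulative hazard,
#'   `n`, `n_events`, `converged`, and the underlying `coxph` fit.
#' @export
fit_cox <- function(cohort, covariates, strata = "sex", cause = "chd",
                    iter_max = 100) {
  if (length(covariates) == 0) stop_grs("no covariates supplied")
  missing_cols <- setdiff(c(covariates, strata), names(cohort))
  if (length(missing_cols))
    stop_grs("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  dat <- cohort
  dat$.status <- as.integer(dat$event == cause)
  if (!is.null(strata)) {
    for (s in unique(dat[[strata]]))
      if (sum(dat$.status[dat[[strata]] == s]) < 1)
        stop_grs("stratum '", s, "' has no events of cause '", cause, "'")
  }
  const <- vapply(covariates, function(v) {
    x <- dat[[v]]
    length(unique(x[!is.na(x)])) < 2
  }, TRUE)
  if (any(const))
    stop_grs("constant covariate(s): ",
             paste(covariates[const], collapse = ", "))
  rhs <- paste(covariates, collapse = " + ")
  if (!is.null(strata)) rhs <- paste0(rhs, " + strata(", strata, ")")
  f <- as.formula(paste("Surv(entry_age, exit_age, .status) ~", rhs))
  # ages are continuous years, so survival's near-tie coarsening (aeqSurv)
  # is disabled; it can collapse very short but valid (entry, exit]
  # intervals to zero length in large simulated cohorts
  fit <- coxph(f, data = dat, ties = "efron",
               control = coxph.control(iter.max = iter_max, eps = 1e-9,
                                       timefix = FALSE))
  converged <- is.null(fit$info) && fit$iter < iter_max
  if (any(is.na(coef(fit))))
    stop_grs("Cox fit failed: singular or separated covariate(s)")
  if (any(abs(coef(fit)) > 15))
    stop_grs("Cox fit suggests complete separation (|log HR| > 15)")
  if (fit$iter >= iter_max)
    stop_grs("Cox fit did not converge in ", iter_max, " iterations")
  b <- coef(fit); se <- sqrt(diag(vcov(fit)))
  hr <- data.frame(term = names(b), log_hr = unname(b), se = unname(se),
                   hr = exp(unname(b)),
                   lo = exp(unname(b) - 1.96 * unname(se)),
                   hi = exp(unname(b) + 1.96 * unname(se)),
                   z = unname(b / se),
                   p = 2 * pnorm(-abs(unname(b / se))))
  out <- structure(list(coefficients = b, vcov = vcov(fit), hr = hr,
                        n = fit$n, n_events = fit$nevent,
                        converged = TRUE, covariates = covariates,
                        strata_col = strata, cause = cause, coxph = fit,
                        model_frame = dat),
                   class = "cox_fit")
  out$baseline <- baseline_cumhaz(out)
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit (cause '%s'): %d subjects, %d events\n",
              x$cause, x$n, x$n_events))
  print(x$hr, row.names = FALSE, digits = 4)
  invisible(x)
}

cox_lp <- function(fit, newdata) {
  # uncentered linear predictor (covariates at zero define the baseline)
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit$coxph)),
                            data = newdata, xlev = fit$coxph$xlevels)
  keep <- match(names(fit$coefficients), colnames(mm))
  if (anyNA(keep)) stop_grs("newdata incompatible with fitted covariates")
  drop(mm[, keep, drop = FALSE] %*% fit$coefficients)
}

#' Breslow baseline cumulative hazard, per stratum
#'
#' At each event age `a` within a stratum the hazard increment is
#' `d_a / sum_{j in risk set} exp(lp_j)` with the risk set
#' `{j : entry < a <= exit}` and the uncentered linear predictor, i.e. the
#' cumulative hazard for a subject whose covariates are all zero. With all
#' coefficients zero this reduces to the Nelson-Aalen estimator.
#'
#' @param fit a `cox_fit`.
#' @return data frame `stratum`, `age`, `increment`, `cumhaz`.
#' @export
baseline_cumhaz <- function(fit) {
  dat <- fit$model_frame
  lp <- cox_lp(fit, dat)
  strat <- if (is.null(fit$strata_col)) rep("all", nrow(dat)) else
    as.character(dat[[fit$strata_col]])
  out <- lapply(unique(strat), function(s) {
    in_s <- strat == s
    entry <- dat$entry_age[in_s]; exit <- dat$exit_age[in_s]
    status <- dat$.status[in_s]; elp <- exp(lp[in_s])
    times <- sort(unique(exit[status == 1]))
    if (length(times) == 0)
      return(data.frame(stratum = s, age = numeric(0),
                        increment = numeric(0), cumhaz = numeric(0)))
    inc <- vapply(times, function(a) {
      d <- sum(status == 1 & exit == a)
      denom <- sum(elp[entry < a & a <= exit])
      d / denom
    }, 0)
    data.frame(stratum = s, age = times, increment = inc,
               cumhaz = cumsum(inc))
  })
  do.call(rbind, out)
}

baseline_stepfun <- function(baseline, stratum) {
  b <- baseline[baseline$stratum == stratum, , drop = FALSE]
  if (nrow(b) == 0) return(function(a) rep(0, length(a)))
  function(a) {
    idx <- findInterval(a, b$age)
    ifelse(idx == 0, 0, b$cumhaz[pmax(idx, 1)])
  }
}

#' Model-based 10-year risk from a fitted Cox model
#'
#' `risk = 1 - exp(-(H0(a0 + horizon) - H0(a0)) * exp(lp))` with `a0` the
#' subject's entry age and `H0` the stratum's Breslow baseline cumulative
#' hazard. Ages beyond the last observed event age use the last cumulative
#' hazard value (flat extrapolation); affected subjects are counted in the
#' `"n_extrapolated"` attribute.
#'
#' @param fit a `cox_fit`.
#' @param newdata cohort-like data frame with the model covariates,
#'   `entry_age` and the stratum column.
#' @param horizon years from entry (default 10).
#' @return numeric risk vector in `[0, 1]` with attribute `n_extrapolated`.
#' @export
predict_risk10 <- function(fit, newdata, horizon = 10) {
  lp <- cox_lp(fit, newdata)
  strat <- if (is.null(fit$strata_col)) rep("all", nrow(newdata)) else
    as.character(newdata[[fit$strata_col]])
  risk <- numeric(nrow(newdata))
  extrap <- 0L
  for (s in unique(strat)) {
    in_s <- strat == s
    H <- baseline_stepfun(fit$baseline, s)
    a0 <- newdata$entry_age[in_s]; a1 <- a0 + horizon
    last_age <- suppressWarnings(
      max(fit$baseline$age[fit$baseline$stratum == s], -Inf))
    extrap <- extrap + sum(a1 > last_age)
    dH <- H(a1) - H(a0)
    risk[in_s] <- 1 - exp(-dH * exp(lp[in_s]))
  }
  attr(risk, "n_extrapolated") <- extrap
  risk
}

#' Wald test for a GRS-by-factor interaction in the Cox model
#'
#' Fits the age-timescale, sex-stratified Cox model with the score, the
#' factor and their product, and returns the Wald z and two-sided p-value
#' of the product term.
#'
#' @param cohort cohort data frame.
#' @param grs_col column with the (standardized) score.
#' @param factor_col column with the interacting risk factor.
#' @param covariates extra adjustment columns.
#' @param cause,strata as in [fit_cox()].
#' @return list `estimate` (product-term log HR), `se`, `z`, `p`, `fit`.
#' @export
interaction_test <- function(cohort, grs_col, factor_col,
                             covariates = character(0), strata = "sex",
                             cause = "chd") {
  x <- cohort[[factor_col]]
  if (length(unique(x[!is.na(x)])) < 2)
    stop_grs("factor '", factor_col, "' does not vary")
  cohort$.inter <- cohort[[grs_col]] * cohort[[factor_col]]
  fit <- fit_cox(cohort, c(grs_col, factor_col, ".inter", covariates),
                 strata = strata, cause = cause)
  row <- fit$hr[fit$hr$term == ".inter", ]
  list(estimate = row$log_hr, se = row$se, z = row$z, p = row$p, fit = fit)
}
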