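# Nonparametric curves on the attained-age scale with delayed entry:
# Kaplan-Meier survival (via survival::survfit, Greenwood CI on the log
# scale) and the Aalen-Johansen cause-specific cumulative incidence.

#' Kaplan-Meier curve on the age scale with delayed entry
#'
#' Product-limit estimator of the cause-specific survival (other causes
#' censored) using `Surv(entry, exit, event == cause)`, with Greenwood
#' standard errors and a log-scale 95% confidence band.
#'
#' @param cohort cohort data frame.
#' @param cause event counted (default `"chd"`).
#' @param cuminc if `TRUE` return cumulative incidence `1 - S` instead of
#'   survival.
#' @return object of class `surv_curve`: data frame `age`, `estimate`,
#'   `lo`, `hi`, `n_risk`, `n_event` with attribute `type`.
#' @export
km_curve <- function(cohort, cause = "chd", cuminc = FALSE) {
  if (nrow(cohort) == 0) stop_grs("empty cohort")
  status <- as.integer(cohort$event == cause)
  sf <- survfit(Surv(cohort$entry_age, cohort$exit_age, status) ~ 1,
                conf.type = "log")
  est <- sf$surv; lo <- sf$lower; hi <- sf$upper
  if (cuminc) { est <- 1 - est; tmp <- lo; lo <- 1 - hi; hi <- 1 - tmp }
  out <- data.frame(age = sf$time, estimate = est, lo = lo, hi = hi,
                    n_risk = sf$n.risk, n_event = sf$n.event)
  structure(out, class = c("surv_curve", "data.frame"),
            type = if (cuminc) "cuminc" else "survival", cause = cause)
}

#' Aalen-Johansen cumulative incidence with competing risks
#'
#' Left-truncated empirical estimator:
#' `CIF_c(t) = sum_{event ages a <= t} S(a-) d_c(a) / n(a)` where `S` is
#' the all-cause Kaplan-Meier survival and `n(a)` the age-`a` risk set
#' (`entry < a <= exit`). With no competing events this equals `1 - KM`
#' exactly. The optional confidence band is a normal approximation using
#' the standard error of the multistate `survival::survfit` estimator.
#'
#' @param cohort cohort data frame with `event` in
#'   `{"chd", "death_other", "censored"}` (any labels; non-`cause`,
#'   non-censored labels are competing events).
#' @param cause cause of interest (default `"chd"`).
#' @param conf if `TRUE`, attach a 95% band (needs at least one event).
#' @return a `surv_curve` of type `"cuminc"`.
#' @export
aj_cif <- function(cohort, cause = "chd", conf = FALSE) {
  if (nrow(cohort) == 0) stop_grs("empty cohort")
  entry <- cohort$entry_age; exit <- cohort$exit_age
  ev <- as.character(cohort$event)
  if (!any(ev != "censored")) stop_grs("no events of any cause present")
  times <- sort(unique(exit[ev != "censored"]))
  n_at <- vapply(times, function(a) sum(entry < a & a <= exit), 0)
  d_all <- vapply(times, function(a) sum(exit == a & ev != "censored"), 0)
  d_cause <- vapply(times, function(a) sum(exit == a & ev == cause), 0)
  s_all <- cumprod(1 - d_all / n_at)          # all-cause KM at each age
  s_minus <- c(1, head(s_all, -1))            # S(a-)
  inc <- s_minus * d_cause / n_at
  cif <- cumsum(inc)
  lo <- hi <- rep(NA_real_, length(times))
  if (conf) {
    se <- aj_se_survfit(cohort, cause, times)
    lo <- pmax(cif - 1.96 * se, 0)
    hi <- pmin(cif + 1.96 * se, 1)
  }
  out <- data.frame(age = times, estimate = cif, lo = lo, hi = hi,
                    n_risk = n_at, n_event = d_cause)
  structure(out, class = c("surv_curve", "data.frame"),
            type = "cuminc", cause = cause)
}

# standard error of the Aalen-Johansen CIF from the multistate survfit
aj_se_survfit <- function(cohort, cause, times) {
  states <- c("censored", setdiff(unique(as.character(cohort$event)),
                                  "censored"))
  evf <- factor(as.character(cohort$event), levels = states)
  sf <- survfit(Surv(cohort$entry_age, cohort$exit_age, evf) ~ 1,
                id = seq_len(nrow(cohort)))
  col <- match(cause, sf$states)
  if (is.na(col)) return(rep(NA_real_, length(times)))
  idx <- findInterval(times, sf$time)
  se <- sf$std.err[, col]
  ifelse(idx == 0, 0, se[pmax(idx, 1)])
}

#' Age at which a cumulative-incidence curve crosses a risk level
#'
#' Smallest age at which the cumulative incidence reaches `level`;
#' `NA_real_` when the curve never attains it within follow-up (e.g. a
#' low-risk group that never reaches 10% cumulative risk by the censoring
#' age).
#'
#' @param curve a `surv_curve`; survival-type curves are converted to
#'   cumulative incidence.
#' @param level risk level in `(0, 1)`.
#' @return age in years, or `NA_real_`.
#' @export
age_at_crossing <- function(curve, level) {
  if (level <= 0 || level >= 1) stop_grs("level must lie in (0, 1)")
  est <- if (identical(attr(curve, "type"), "survival"))
    1 - curve$estimate else curve$estimate
  hit <- which(est >= level)
  if (length(hit) == 0) return(NA_real_)
  curve$age[hit[1]]
}
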