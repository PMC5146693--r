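# 10-year-risk reclassification machinery: risk-category bins, paired
# event/non-event cross-tabulations, categorical and continuous net
# reclassification improvement (NRI) and the integrated discrimination
# improvement (IDI), with Pencina-style normal-approximation intervals.

#' Risk-category cut points
#'
#' Cut points are percentages, strictly increasing, starting at 0 and
#' ending at 100. The default `(0, 7.5, 10, 20, 100)` gives the four
#' categories 0-7.5%, 7.5-10%, 10-20%, 20-100%.
#'
#' @param cuts numeric vector of percentages.
#' @return object of class `risk_bins` with pretty labels.
#' @export
risk_bins <- function(cuts = c(0, 7.5, 10, 20, 100)) {
  if (length(cuts) < 2 || any(diff(cuts) <= 0) ||
      cuts[1] != 0 || cuts[length(cuts)] != 100)
    stop_grs("cuts must be strictly increasing, starting at 0 and ending at 100")
  labels <- paste0(format(cuts[-length(cuts)], trim = TRUE, drop0trailing = TRUE),
                   "-", format(cuts[-1], trim = TRUE, drop0trailing = TRUE), "%")
  structure(list(cuts = cuts, labels = labels), class = "risk_bins")
}

#' Assign risks to categories
#'
#' Half-open intervals `[lo, hi)` with the last bin closed at 100%, so a
#' risk of exactly 7.5% falls in the second category and a risk of 100% in
#' the last.
#'
#' @param risk probabilities in `[0, 1]` (`NA` allowed, propagated).
#' @param bins a [risk_bins()].
#' @return integer categories (1-based factor with bin labels).
#' @export
assign_bins <- function(risk, bins = risk_bins()) {
  bad <- !is.na(risk) & (risk < 0 | risk > 1)
  if (any(bad))
    stop_grs("risk outside [0, 1] for ", sum(bad), " subject(s)")
  k <- length(bins$cuts) - 1
  cat <- pmin(findInterval(risk, bins$cuts / 100), k)
  factor(bins$labels[cat], levels = bins$labels)
}

#' Paired reclassification cross-tabulations
#'
#' Separate old-category x new-category count tables for subjects with and
#' without the 10-year event, plus the all-subject table and per-row
#' reclassified percentages `100 * (1 - diagonal / row total)`. Subjects
#' with a missing risk or event status are excluded and counted.
#'
#' @param old_risk,new_risk 10-year risks under the reference and updated
#'   model.
#' @param event10 indicator of an event within the classification horizon;
#'   subjects censored earlier count as non-events.
#' @param bins a [risk_bins()].
#' @return object of class `reclass_table`: matrices `events`, `nonevents`,
#'   `all`, data frame `reclass_pct`, and `n_excluded`.
#' @export
reclass_table <- function(old_risk, new_risk, event10, bins = risk_bins()) {
  if (length(old_risk) != length(new_risk) ||
      length(old_risk) != length(event10))
    stop_grs("old_risk, new_risk and event10 must have equal length")
  ok <- !is.na(old_risk) & !is.na(new_risk) & !is.na(event10)
  n_excl <- sum(!ok)
  oc <- assign_bins(old_risk[ok], bins)
  nc <- assign_bins(new_risk[ok], bins)
  ev <- as.integer(event10[ok]) == 1
  tab <- function(sel) unclass(table(old = oc[sel], new = nc[sel]))
  events <- tab(ev); nonevents <- tab(!ev)
  all_tab <- events + nonevents
  pct <- function(m) {
    rs <- rowSums(m)
    ifelse(rs > 0, 100 * (1 - diag(m) / rs), 0)
  }
  reclass_pct <- data.frame(old_category = bins$labels,
                            events = pct(events),
                            nonevents = pct(nonevents),
                            all = pct(all_tab), row.names = NULL)
  structure(list(events = events, nonevents = nonevents, all = all_tab,
                 reclass_pct = reclass_pct, n_excluded = n_excl,
                 bins = bins),
            class = "reclass_table")
}

#' @export
print.reclass_table <- function(x, ...) {
  cat(sprintf("reclass_table: %d events, %d non-events (%d excluded)\n",
              sum(x$events), sum(x$nonevents), x$n_excluded))
  cat("events:\n"); print(x$events)
  cat("non-events:\n"); print(x$nonevents)
  invisible(x)
}

ups_downs <- function(m) {
  list(up = sum(m[upper.tri(m)]), down = sum(m[lower.tri(m)]), n = sum(m))
}

#' Categorical net reclassification improvement
#'
#' `NRI_events = (up - down) / n_events` over the event table,
#' `NRI_nonevents = (down - up) / n_nonevents` over the non-event table,
#' and their sum, with the standard binomial-difference variance
#' `var = (up + down)/n^2 - (up - down)^2/n^3` per stratum, normal CIs and
#' two-sided p-values.
#'
#' @param table a [reclass_table()] (or any list with `events` and
#'   `nonevents` count matrices).
#' @return object of class `nri_result` with `events`, `nonevents`,
#'   `total`, each `estimate`, `se`, `ci`, `p`.
#' @export
categorical_nri <- function(table) {
  e <- ups_downs(table$events); ne <- ups_downs(table$nonevents)
  if (e$n == 0 || ne$n == 0)
    stop_grs("need at least one event and one non-event")
  nri_e <- (e$up - e$down) / e$n
  nri_ne <- (ne$down - ne$up) / ne$n
  var_e <- (e$up + e$down) / e$n^2 - (e$up - e$down)^2 / e$n^3
  var_ne <- (ne$up + ne$down) / ne$n^2 - (ne$down - ne$up)^2 / ne$n^3
  nri_components(nri_e, sqrt(var_e), nri_ne, sqrt(var_ne),
                 kind = "categorical")
}

nri_components <- function(est_e, se_e, est_ne, se_ne, kind) {
  total <- est_e + est_ne
  se_t <- sqrt(se_e^2 + se_ne^2)
  piece <- function(est, se) {
    z <- if (se > 0) est / se else 0
    list(estimate = est, se = se, ci = est + c(-1.96, 1.96) * se,
         p = if (se > 0) 2 * pnorm(-abs(z)) else as.numeric(est == 0))
  }
  structure(list(events = piece(est_e, se_e),
                 nonevents = piece(est_ne, se_ne),
                 total = piece(total, se_t), kind = kind),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  f <- function(lab, p)
    cat(sprintf("  %-10s %+0.4f [%+0.4f, %+0.4f], p = %.3g\n", lab,
                p$estimate, p$ci[1], p$ci[2], p$p))
  cat(sprintf("%s NRI:\n", x$kind))
  f("events", x$events); f("non-events", x$nonevents); f("total", x$total)
  invisible(x)
}

#' Continuous (category-free) net reclassification improvement
#'
#' Event term `P(new > old | event) - P(new < old | event)`; non-event term
#' `P(new < old | non-event) - P(new > old | non-event)`; ties contribute
#' zero. Normal-approximation CI per stratum.
#'
#' @inheritParams reclass_table
#' @return an `nri_result` (kind `"continuous"`).
#' @export
continuous_nri <- function(old_risk, new_risk, event10) {
  ok <- !is.na(old_risk) & !is.na(new_risk) & !is.na(event10)
  d <- sign(new_risk[ok] - old_risk[ok])
  ev <- as.integer(event10[ok]) == 1
  if (!any(ev) || all(ev))
    stop_grs("need at least one event and one non-event")
  term <- function(dd, sgn) {
    n <- length(dd)
    est <- sgn * mean(dd)
    se <- sqrt((mean(dd^2) - mean(dd)^2) / n)
    list(est = est, se = se)
  }
  e <- term(d[ev], 1); ne <- term(d[!ev], -1)
  nri_components(e$est, e$se, ne$est, ne$se, kind = "continuous")
}

#' Integrated discrimination improvement
#'
#' Difference between models in the discrimination slope:
#' `(mean new - mean old risk | events) - (mean new - mean old | non-events)`,
#' with the two-sample paired-difference standard error.
#'
#' @inheritParams reclass_table
#' @return list `idi`, `se`, `ci`, `p`.
#' @export
idi <- function(old_risk, new_risk, event10) {
  ok <- !is.na(old_risk) & !is.na(new_risk) & !is.na(event10)
  d <- new_risk[ok] - old_risk[ok]
  ev <- as.integer(event10[ok]) == 1
  if (!any(ev) || all(ev))
    stop_grs("need at least one event and one non-event")
  est <- mean(d[ev]) - mean(d[!ev])
  se <- sqrt(var(d[ev]) / sum(ev) + var(d[!ev]) / sum(!ev))
  z <- if (se > 0) est / se else 0
  list(idi = est, se = se, ci = est + c(-1.96, 1.96) * se,
       p = if (se > 0) 2 * pnorm(-abs(z)) else as.numeric(est == 0))
}
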