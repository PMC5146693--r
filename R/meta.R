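# Fixed-effect inverse-variance meta-analysis with Cochran's Q and I^2.
# Hazard ratios are pooled on the log scale; a helper recovers the SE from
# published 95% CI bounds.

#' Fixed-effect inverse-variance meta-analysis
#'
#' Weights `w_i = 1/se_i^2`; pooled estimate `sum(w * theta) / sum(w)` with
#' `se = 1/sqrt(sum(w))` and a normal 95% CI. With two or more studies the
#' result carries Cochran's Q, its chi-square p-value and I^2.
#'
#' @param estimate study estimates on the analysis scale (log HR, delta C,
#'   NRI, ...).
#' @param se standard errors, all positive.
#' @param labels optional study labels.
#' @return object of class `meta_result`: `estimate`, `se`, `ci`, `p`,
#'   `k`, and (k >= 2) `q`, `df`, `i2`, `p_q`; plus the per-study table.
#' @export
fixed_effect_meta <- function(estimate, se, labels = NULL) {
  if (length(estimate) < 1) stop_grs("need at least one study")
  if (length(se) != length(estimate))
    stop_grs("estimate and se must have equal length")
  if (any(!is.finite(se)) || any(se <= 0))
    stop_grs("all standard errors must be positive and finite")
  w <- 1 / se^2
  pooled <- sum(w * estimate) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled / pooled_se
  out <- list(estimate = pooled, se = pooled_se,
              ci = pooled + c(-1.96, 1.96) * pooled_se,
              p = 2 * pnorm(-abs(z)), k = length(estimate),
              studies = data.frame(
                label = labels %||% paste0("study", seq_along(estimate)),
                estimate = estimate, se = se, weight = w / sum(w)))
  if (length(estimate) >= 2) {
    het <- heterogeneity(estimate, se, pooled)
    out[c("q", "df", "i2", "p_q")] <- het[c("q", "df", "i2", "p_q")]
  }
  structure(out, class = "meta_result")
}

#' Heterogeneity statistics for a set of study estimates
#'
#' Cochran's `Q = sum w_i (theta_i - pooled)^2` with `k - 1` degrees of
#' freedom, its upper-tail chi-square p-value, and
#' `I^2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param estimate,se study estimates and standard errors (k >= 2).
#' @param pooled pooled estimate; recomputed by inverse-variance weighting
#'   when omitted.
#' @return list `q`, `df`, `i2` (percent), `p_q`.
#' @export
heterogeneity <- function(estimate, se, pooled = NULL) {
  if (length(estimate) < 2)
    stop_grs("heterogeneity undefined with fewer than 2 studies")
  w <- 1 / se^2
  if (is.null(pooled)) pooled <- sum(w * estimate) / sum(w)
  q <- sum(w * (estimate - pooled)^2)
  df <- length(estimate) - 1
  c(list(q = q, df = df), heterogeneity_from_q(q, df))
}

#' I-squared and p-value from a Cochran's Q statistic
#'
#' @param q Cochran's Q.
#' @param df degrees of freedom (number of studies minus one).
#' @return list `i2` (percent in `[0, 100)`), `p_q`.
#' @export
heterogeneity_from_q <- function(q, df) {
  if (df < 1) stop_grs("df must be at least 1")
  list(i2 = max(0, (q - df) / q) * 100,
       p_q = pchisq(q, df, lower.tail = FALSE))
}

#' Standard error of a log hazard ratio from published CI bounds
#'
#' `se = (log(hi) - log(lo)) / (2 * 1.96)` — the conventional way a
#' published 95% CI is consumed for inverse-variance pooling.
#'
#' @param lo,hi CI bounds on the ratio scale.
#' @return standard error on the log scale.
#' @export
se_from_ci <- function(lo, hi) {
  if (any(lo <= 0) || any(hi <= lo))
    stop_grs("need 0 < lo < hi on the ratio scale")
  (log(hi) - log(lo)) / (2 * 1.96)
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("fixed-effect meta-analysis of %d studies:\n", x$k))
  cat(sprintf("  pooled %.4f [%.4f, %.4f], p = %.3g\n",
              x$estimate, x$ci[1], x$ci[2], x$p))
  if (!is.null(x$q))
    cat(sprintf("  Q = %.3f (df %d, p = %.3g), I^2 = %.1f%%\n",
                x$q, x$df, x$p_q, x$i2))
  invisible(x)
}
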