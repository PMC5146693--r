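# Truncated Harrell's C-index and the correlated jackknife test for the
# difference in C between two risk scores on the same subjects. Both are
# built on per-subject concordant/comparable pair tallies so leave-one-out
# values are exact and cheap.

# per-subject tallies of comparable pairs and concordance contributions:
# pair (i, j) comparable iff i has the event at t_i <= horizon and
# t_j > t_i; concordant if score_i > score_j, 0.5 for score ties
pair_tallies <- function(time, status, score, horizon) {
  n <- length(time)
  conc <- numeric(n); pairs <- numeric(n)
  ev <- which(status == 1 & time <= horizon)
  for (i in ev) {
    j <- which(time > time[i])
    if (!length(j)) next
    cij <- (score[i] > score[j]) + 0.5 * (score[i] == score[j])
    conc[i] <- conc[i] + sum(cij)
    pairs[i] <- pairs[i] + length(j)
    conc[j] <- conc[j] + cij
    pairs[j] <- pairs[j] + 1
  }
  list(conc = conc, pairs = pairs,
       total_conc = sum(conc) / 2, total_pairs = sum(pairs) / 2)
}

#' Truncated Harrell's C-index
#'
#' Concordance restricted to events within `horizon` years of follow-up: a
#' pair is comparable iff one subject has the event at follow-up time
#' `t_i <= horizon` and the other is still at risk at `t_i` (`t_j > t_i`);
#' it is concordant when the event subject has the higher score, with score
#' ties counting 0.5. The standard error is a leave-one-out jackknife.
#'
#' @param time follow-up time from entry, years.
#' @param status 1 = event of interest, 0 = censored/competing.
#' @param score risk score (higher = riskier).
#' @param horizon truncation horizon in years (default 10; `Inf` for none).
#' @return object of class `cindex_result`: `c`, `n_pairs`, `se`, `n`.
#' @export
cindex_truncated <- function(time, status, score, horizon = 10) {
  stopifnot(length(time) == length(status), length(time) == length(score))
  t <- pair_tallies(time, status, score, horizon)
  if (t$total_pairs == 0)
    stop_grs("no comparable pairs: C-index undefined")
  cc <- t$total_conc / t$total_pairs
  loo_pairs <- t$total_pairs - t$pairs
  loo <- ifelse(loo_pairs > 0, (t$total_conc - t$conc) / loo_pairs, cc)
  n <- length(time)
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  structure(list(c = cc, n_pairs = t$total_pairs, se = se, n = n,
                 horizon = horizon),
            class = "cindex_result")
}

#' @export
print.cindex_result <- function(x, ...) {
  cat(sprintf("C-index (<= %s y): %.4f (se %.4f, %g comparable pairs)\n",
              format(x$horizon), x$c, x$se, x$n_pairs))
  invisible(x)
}

#' Correlated jackknife test for a difference in C-index
#'
#' `delta_c = C_B - C_A` for two scores on the same subjects. Leave-one-out
#' values of the difference give the jackknife variance
#' `var = (n-1)/n * sum((dC_(-i) - mean)^2)`; the test statistic
#' `z = delta_c / se` is referred to the normal distribution. When the two
#' scores give identical concordance contributions (`delta_c` exactly 0
#' with zero jackknife variance) the p-value is defined as 1.
#'
#' @param time,status,horizon as in [cindex_truncated()].
#' @param score_a reference model score.
#' @param score_b comparison model score.
#' @return object of class `delta_c_result`: `delta_c`, `se`, `z`, `p`,
#'   `c_a`, `c_b`.
#' @export
delta_c_jackknife <- function(time, status, score_a, score_b, horizon = 10) {
  n <- length(time)
  if (n < 3) stop_grs("need at least 3 subjects for the jackknife")
  ta <- pair_tallies(time, status, score_a, horizon)
  tb <- pair_tallies(time, status, score_b, horizon)
  if (ta$total_pairs == 0)
    stop_grs("no comparable pairs: C-index undefined")
  ca <- ta$total_conc / ta$total_pairs
  cb <- tb$total_conc / tb$total_pairs
  dc <- cb - ca
  loo_pairs <- ta$total_pairs - ta$pairs   # same pair structure for both
  loo_a <- ifelse(loo_pairs > 0, (ta$total_conc - ta$conc) / loo_pairs, ca)
  loo_b <- ifelse(loo_pairs > 0, (tb$total_conc - tb$conc) / loo_pairs, cb)
  loo_d <- loo_b - loo_a
  se <- sqrt((n - 1) / n * sum((loo_d - mean(loo_d))^2))
  if (se == 0) {
    z <- 0; p <- if (dc == 0) 1 else 0
  } else {
    z <- dc / se; p <- 2 * pnorm(-abs(z))
  }
  structure(list(delta_c = dc, se = se, z = z, p = p, c_a = ca, c_b = cb,
                 n = n, horizon = horizon),
            class = "delta_c_result")
}

#' @export
print.delta_c_result <- function(x, ...) {
  cat(sprintf("delta C = %+.4f (C_B %.4f vs C_A %.4f), jackknife se %.4f, z = %.3f, p = %.3g\n",
              x$delta_c, x$c_b, x$c_a, x$se, x$z, x$p))
  invisible(x)
}
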