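#' Binary AUC with a DeLong-style confidence interval
#'
#' Mann-Whitney AUC computed from midranks (ties count 0.5), with the
#' DeLong placement-based variance and a normal 95% CI clipped to
#' `[0, 1]`.
#'
#' @param labels binary vector (0/1 or logical).
#' @param scores numeric scores, higher = more likely positive.
#' @return object of class `auc_result`: `auc`, `se`, `ci`, `n_pos`,
#'   `n_neg`.
#' @export
auc_binary <- function(labels, scores) {
  ok <- !is.na(labels) & !is.na(scores)
  labels <- as.integer(labels[ok]); scores <- scores[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_grs("both classes required to compute an AUC")
  r <- rank(scores)                       # midranks handle ties
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  se <- sqrt(var(v10) / n1 + var(v01) / n0)
  ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
  structure(list(auc = auc, se = se, ci = ci, n_pos = n1, n_neg = n0),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (95%% CI %.4f-%.4f; %d pos / %d neg)\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Per-SD logistic odds ratio
#'
#' Standardizes the score to unit SD, fits a maximum-likelihood logistic
#' regression (optionally adjusted), and reports the odds ratio per SD with
#' a Wald 95% CI. Complete separation is signalled as an error.
#'
#' @param labels binary outcome (0/1).
#' @param score numeric score; standardized internally, so rescaling the
#'   raw score leaves the result unchanged.
#' @param adjust optional data frame of adjustment covariates.
#' @return object of class `or_result`: `or`, `log_or`, `se`, `ci`, `p`.
#' @export
logistic_per_sd <- function(labels, score, adjust = NULL) {
  if (sd(score, na.rm = TRUE) == 0)
    stop_grs("score has zero SD")
  s <- (score - mean(score, na.rm = TRUE)) / sd(score, na.rm = TRUE)
  dat <- data.frame(.y = as.integer(labels), .s = s)
  rhs <- ".s"
  if (!is.null(adjust)) {
    dat <- cbind(dat, adjust)
    rhs <- paste(c(".s", colnames(adjust)), collapse = " + ")
  }
  fit <- suppressWarnings(glm(as.formula(paste(".y ~", rhs)),
                              data = dat, family = binomial()))
  mu <- fit$fitted.values
  if (any(mu > 1 - 1e-10) || any(mu < 1e-10) || abs(coef(fit)[".s"]) > 15)
    stop_grs("logistic fit suggests complete separation")
  b <- coef(fit)[".s"]; se <- sqrt(diag(vcov(fit))[".s"])
  structure(list(or = exp(unname(b)), log_or = unname(b), se = unname(se),
                 ci = exp(unname(b) + c(-1.96, 1.96) * unname(se)),
                 p = 2 * pnorm(-abs(unname(b / se)))),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR per SD = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$or, x$ci[1], x$ci[2], x$p))
  invisible(x)
}
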