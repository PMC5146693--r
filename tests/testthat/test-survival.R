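# survival engine: age-timescale Cox with delayed entry, Breslow baseline,
# model-based 10-year risks, KM / Aalen-Johansen curves, crossing ages,
# interaction tests

fix6 <- function() {
  # 6 records, one binary covariate, untied event ages, delayed entry;
  # event order mixes x groups so the partial likelihood has a finite root
  make_cohort(entry = c(40, 42, 45, 41, 48, 50),
              exit = c(55, 60, 52, 63, 58, 66),
              event = c("chd", "censored", "chd", "chd", "censored", "chd"),
              x = c(1, 1, 0, 1, 0, 0))
}

test_that("Cox coefficient equals the root of the hand-written score", {
  coh <- fix6()
  fit <- fit_cox(coh, "x", strata = NULL)
  # partial-likelihood score: sum over events of x_i - weighted risk-set mean
  score_fn <- function(b) {
    s <- 0
    for (i in which(coh$event == "chd")) {
      a <- coh$exit_age[i]
      rs <- which(coh$entry_age < a & a <= coh$exit_age)
      w <- exp(b * coh$x[rs])
      s <- s + coh$x[i] - sum(coh$x[rs] * w) / sum(w)
    }
    s
  }
  root <- uniroot(score_fn, c(-5, 5), tol = 1e-12)$root
  expect_equal(unname(coef(fit$coxph)), root, tolerance = 1e-6)
})

test_that("two-group Weibull simulation recovers the true log hazard ratio", {
  set.seed(14)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  u <- runif(n)
  t <- 70 * (-log(u) * exp(-0.5 * x))^(1 / 4)
  coh <- make_cohort(entry = rep(1e-6, n), exit = t,
                     event = rep("chd", n), x = x)
  fit <- fit_cox(coh, "x", strata = NULL)
  b <- fit$hr$log_hr[1]
  expect_lt(abs(b - 0.5), 3 * fit$hr$se[1])
})

test_that("null covariates give ~95% CI coverage of zero", {
  set.seed(15)
  cover <- vapply(1:200, function(r) {
    n <- 250
    x <- rnorm(n)
    t <- 60 * (-log(runif(n)))^(1 / 3)
    ev <- ifelse(runif(n) < 0.7, "chd", "censored")
    coh <- make_cohort(entry = rep(1e-6, n), exit = t, event = ev, x = x)
    fit <- fit_cox(coh, "x", strata = NULL)
    h <- fit$hr[1, ]
    h$lo <= 1 && 1 <= h$hi
  }, TRUE)
  expect_gte(mean(cover), 0.90)
})

test_that("Breslow baseline matches hand-computed increments", {
  coh <- make_cohort(entry = c(0, 0, 0, 0, 0),
                     exit = c(2, 4, 5, 7, 9),
                     event = c("chd", "censored", "chd", "chd", "censored"),
                     x = c(1, 0, 0, 1, 0))
  fit <- fit_cox(coh, "x", strata = NULL)
  b <- unname(coef(fit$coxph))
  e <- exp(b)
  # risk sets: age 2 -> all 5; age 5 -> {3,4,5}; age 7 -> {4,5}
  inc <- c(1 / (2 * e + 3), 1 / (1 + e + 1), 1 / (e + 1))
  bl <- fit$baseline
  expect_equal(bl$age, c(2, 5, 7))
  expect_equal(bl$increment, inc, tolerance = 1e-10)
  expect_equal(bl$cumhaz, cumsum(inc), tolerance = 1e-10)
  expect_true(all(diff(bl$cumhaz) >= 0))
})

test_that("Breslow baseline agrees with survival::basehaz on untied data", {
  set.seed(16)
  n <- 150
  coh <- make_cohort(entry = runif(n, 30, 50),
                     exit = NA, event = NA, x = rnorm(n))
  coh$exit_age <- coh$entry_age + rexp(n, 0.1) + 1e-4
  coh$event <- ifelse(runif(n) < 0.5, "chd", "censored")
  fit <- fit_cox(coh, "x", strata = NULL)
  bh <- survival::basehaz(fit$coxph, centered = FALSE)
  ours <- fit$baseline
  at <- match(ours$age, bh$time)
  expect_equal(ours$cumhaz, bh$hazard[at], tolerance = 1e-8)
})

test_that("baseline reduces to Nelson-Aalen when the coefficient is zero", {
  coh <- make_cohort(entry = rep(0, 6), exit = c(1, 2, 3, 4, 5, 6),
                     event = rep(c("chd", "censored"), 3),
                     x = c(1, 0, 0, 1, 1, 0))
  fit <- fit_cox(coh, "x", strata = NULL)
  fit$coefficients[] <- 0      # force lp = 0
  bl <- baseline_cumhaz(fit)
  na_inc <- c(1 / 6, 1 / 4, 1 / 2)  # d/n at ages 1, 3, 5
  expect_equal(bl$increment, na_inc, tolerance = 1e-12)
})

test_that("model-based 10-year risk matches the hand formula", {
  coh <- make_cohort(entry = c(40, 40, 40, 40, 45, 45, 45, 45),
                     exit = c(44, 48, 52, 58, 47, 51, 56, 60),
                     event = c("chd", "chd", "censored", "chd",
                               "chd", "censored", "chd", "censored"),
                     x = c(1, 0, 1, 0, 1, 0, 1, 0))
  fit <- fit_cox(coh, "x", strata = NULL)
  new <- make_cohort(entry = c(41, 41), exit = c(51, 51),
                     event = c("censored", "censored"), x = c(1, 0))
  r <- predict_risk10(fit, new, horizon = 10)
  H <- function(a) {
    b <- fit$baseline
    if (!any(b$age <= a)) 0 else max(b$cumhaz[b$age <= a])
  }
  dH <- H(51) - H(41)
  b <- unname(coef(fit$coxph))
  expect_equal(as.numeric(r), 1 - exp(-dH * exp(b * c(1, 0))),
               tolerance = 1e-12)
  # flat baseline over the window -> risk 0
  new0 <- make_cohort(entry = 90, exit = 99, event = "censored", x = 0)
  r0 <- predict_risk10(fit, new0, horizon = 5)
  expect_equal(as.numeric(r0), 0)
  expect_gte(attr(r0, "n_extrapolated"), 1)
})

test_that("cause-specific fit equals standard Cox with competing as censored", {
  set.seed(17)
  n <- 400
  coh <- make_cohort(entry = runif(n, 35, 55), exit = NA, event = NA,
                     x = rnorm(n))
  coh$exit_age <- coh$entry_age + rexp(n, 0.08) + 1e-4
  coh$event <- sample(c("chd", "death_other", "censored"), n, TRUE,
                      prob = c(0.4, 0.25, 0.35))
  f1 <- fit_cox(coh, "x", strata = NULL, cause = "chd")
  coh2 <- coh
  coh2$event[coh2$event == "death_other"] <- "censored"
  f2 <- fit_cox(coh2, "x", strata = NULL, cause = "chd")
  expect_identical(f1$coefficients, f2$coefficients)
})

test_that("Cox fit is invariant to a common shift of the age axis", {
  coh <- fix6()
  fit1 <- fit_cox(coh, "x", strata = NULL)
  shifted <- coh
  shifted$entry_age <- shifted$entry_age + 7
  shifted$exit_age <- shifted$exit_age + 7
  fit2 <- fit_cox(shifted, "x", strata = NULL)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-10)
  expect_equal(fit2$baseline$age, fit1$baseline$age + 7)
})

test_that("degenerate fits raise errors", {
  coh <- fix6()
  coh$z <- 1
  expect_error(fit_cox(coh, "z", strata = NULL), "constant")
  expect_error(fit_cox(coh, "nope", strata = NULL), "lacks")
  onesex <- fix6()
  onesex$sex <- c("male", "male", "male", "female", "female", "female")
  onesex$event <- c("chd", "chd", "chd", "censored", "censored", "censored")
  expect_error(fit_cox(onesex, "x", strata = "sex"), "no events")
})

test_that("KM curve reproduces the hand product-limit and Greenwood band", {
  coh <- make_cohort(entry = c(0, 0, 0), exit = c(1, 2, 3),
                     event = c("chd", "censored", "chd"))
  km <- km_curve(coh)
  expect_equal(km$estimate[km$age == 1], 2 / 3)
  expect_equal(km$estimate[km$age == 3], 0)
  expect_true(all(diff(km$estimate) <= 0))
  ok <- !is.na(km$lo)
  expect_true(all(km$lo[ok] <= km$estimate[ok] + 1e-12 &
                    km$estimate[ok] <= km$hi[ok] + 1e-12))
  # no events -> survival identically 1
  none <- make_cohort(entry = c(0, 0), exit = c(5, 7),
                      event = c("censored", "censored"))
  expect_true(all(km_curve(none)$estimate == 1))
})

test_that("Aalen-Johansen equals 1 - KM without competing events", {
  set.seed(18)
  n <- 120
  coh <- make_cohort(entry = runif(n, 30, 50), exit = NA, event = NA)
  coh$exit_age <- coh$entry_age + rexp(n, 0.1) + 1e-4
  coh$event <- ifelse(runif(n) < 0.6, "chd", "censored")
  cif <- aj_cif(coh, "chd")
  km <- km_curve(coh, "chd", cuminc = TRUE)
  at <- match(cif$age[cif$n_event > 0], km$age)
  expect_equal(cif$estimate[cif$n_event > 0], km$estimate[at],
               tolerance = 1e-12)
})

test_that("Aalen-Johansen matches hand computation on a two-cause fixture", {
  coh <- make_cohort(entry = rep(0, 6), exit = 1:6,
                     event = c("chd", "death_other", "censored",
                               "chd", "death_other", "chd"))
  cif <- aj_cif(coh, "chd")
  # S(a-) d_chd/n: ages 1,2,4,5,6 with n = 6,5,3,2,1
  s <- cumprod(1 - c(1 / 6, 1 / 5, 1 / 3, 1 / 2, 1))
  s_minus <- c(1, head(s, -1))
  inc_chd <- s_minus * c(1 / 6, 0, 1 / 3, 0, 1)
  expect_equal(cif$estimate, cumsum(inc_chd), tolerance = 1e-12)
  # conservation: CIF_chd + CIF_competing = 1 - S at event ages
  cif2 <- aj_cif(coh, "death_other")
  expect_equal(cif$estimate + cif2$estimate, 1 - s, tolerance = 1e-12)
})

test_that("hand AJ equals the multistate survfit estimator", {
  set.seed(19)
  n <- 200
  coh <- make_cohort(entry = runif(n, 30, 55), exit = NA, event = NA)
  coh$exit_age <- coh$entry_age + rexp(n, 0.09) + 1e-4
  coh$event <- sample(c("chd", "death_other", "censored"), n, TRUE,
                      prob = c(0.35, 0.25, 0.4))
  cif <- aj_cif(coh, "chd", conf = TRUE)
  evf <- factor(coh$event, levels = c("censored", "chd", "death_other"))
  sf <- survival::survfit(survival::Surv(entry_age, exit_age, evf) ~ 1,
                          data = coh, id = seq_len(n))
  ours <- cif$estimate[match(sf$time, cif$age)]
  ours[is.na(ours)] <- 0
  theirs <- sf$pstate[, match("chd", sf$states)]
  expect_equal(ours[sf$time %in% cif$age], theirs[sf$time %in% cif$age],
               tolerance = 1e-10)
  ok <- !is.na(cif$lo)
  expect_true(all(cif$lo[ok] <= cif$estimate[ok] &
                    cif$estimate[ok] <= cif$hi[ok]))
})

test_that("age_at_crossing returns the first age at the level or NA", {
  curve <- structure(data.frame(age = c(50, 52, 60),
                                estimate = c(0.05, 0.12, 0.2),
                                lo = NA, hi = NA, n_risk = 1, n_event = 1),
                     class = c("surv_curve", "data.frame"), type = "cuminc")
  expect_equal(age_at_crossing(curve, 0.10), 52)
  low <- curve; low$estimate <- c(0.02, 0.05, 0.08)
  expect_true(is.na(age_at_crossing(low, 0.10)))
  expect_error(age_at_crossing(curve, 1.5), "level")
})

test_that("top-vs-bottom quintile crossing gap is positive under real effects", {
  set.seed(20)
  gaps <- vapply(1:15, function(r) {
    n <- 1200
    s <- rnorm(n)
    entry <- runif(n, 35, 60)
    u <- runif(n)
    exit <- 115 * ((entry / 115)^5 - log(u) * exp(-log(2.2) * s))^(1 / 5)
    coh <- make_cohort(entry = entry, exit = pmin(exit, entry + 20),
                       event = ifelse(exit <= entry + 20, "chd", "censored"),
                       s = s)
    q <- quantile(s, c(0.2, 0.8))
    top <- km_curve(coh[s >= q[2], ], cuminc = TRUE)
    bot <- km_curve(coh[s <= q[1], ], cuminc = TRUE)
    a_top <- age_at_crossing(top, 0.10)
    a_bot <- age_at_crossing(bot, 0.10)
    if (is.na(a_bot)) a_bot <- 80
    a_bot - a_top
  }, 0)
  expect_gt(mean(gaps > 0), 0.9)
})

test_that("interaction test flags simulated interactions and rejects constants", {
  set.seed(22)
  n <- 4000
  grs <- rnorm(n)
  smoke <- rbinom(n, 1, 0.3)
  lp <- 0.3 * grs + 0.4 * smoke + 0.5 * grs * smoke
  u <- runif(n)
  entry <- runif(n, 35, 55)
  exit <- 100 * ((entry / 100)^4 - log(u) * exp(-lp))^(1 / 4)
  coh <- make_cohort(entry = entry, exit = pmin(exit, entry + 15),
                     event = ifelse(exit <= entry + 15, "chd", "censored"),
                     sex = sample(c("male", "female"), n, TRUE),
                     grs = grs, smoke = smoke)
  it <- interaction_test(coh, "grs", "smoke")
  expect_lt(it$p, 0.05)
  expect_lt(abs(it$estimate - 0.5), 4 * it$se)
  coh$const <- 1
  expect_error(interaction_test(coh, "grs", "const"), "does not vary")
})
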