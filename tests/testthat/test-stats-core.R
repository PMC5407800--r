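# Fitting engines: Cox partial likelihood, logistic MLE, LRT, AUC, KM,
# Pearson chi-square, classification metrics.

test_that("Cox fit matches a brute-force partial-likelihood maximizer", {
  # identical (time, event) multisets in both groups: beta-hat = 0 by symmetry
  ga <- encode_groups(c(1, 1, 2, 2), 1.5)
  f0 <- fit_cox(ga, time = c(1, 2, 1, 2), event = c(1, 1, 1, 1))
  expect_lt(abs(f0$beta), 1e-6)
  expect_equal(f0$hr, exp(f0$beta))
  expect_gte(f0$loglik, f0$loglik_null)

  # 1-D oracle: dense grid over the partial likelihood (no ties)
  # alternating groups so the partial likelihood has a finite interior max
  time <- c(1, 2, 3, 4); event <- rep(1, 4); x <- c(1, 0, 1, 0)
  ga <- encode_groups(x, 0.5)
  fit <- fit_cox(ga, time, event)
  grid <- seq(-10, 10, by = 1e-3)
  ll <- vapply(grid, cox_pll_1d, numeric(1), x = x, time = time, event = event)
  expect_lt(abs(fit$beta - grid[which.max(ll)]), 1e-3)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)

  expect_error(fit_cox(ga, time, event = rep(0, 4)), "no events")
})

test_that("Cox fit agrees with coxph under both dummy codings and adjusters", {
  co <- make_surv_cohort(seed = 21, n = 120)
  cum <- fit_cox(encode_groups(co$z, c(20, 28), "cumulative"), co$time, co$event)
  hot <- fit_cox(encode_groups(co$z, c(20, 28), "onehot"), co$time, co$event)
  expect_equal(cum$loglik, hot$loglik, tolerance = 1e-8)
  expect_equal(cum$loglik_null, hot$loglik_null, tolerance = 1e-10)
  # cumulative betas are increments; one-hot betas are vs reference
  expect_equal(unname(cumsum(cum$beta)), unname(hot$beta), tolerance = 1e-6)
  # adjusted fit runs and reports more coefficients
  cov <- data.frame(age = rnorm(120, 55, 10))
  fadj <- fit_cox(encode_groups(co$z, c(20, 28)), co$time, co$event, cov)
  expect_length(fadj$beta, 3L)
})

test_that("logistic saturated fit equals the closed-form group fractions", {
  ga <- encode_groups(c(1, 1, 1, 1, 2, 2, 2, 2), 1.5)
  y <- c(1, 0, 0, 0, 1, 1, 1, 0)  # fractions 1/4 and 3/4
  f <- fit_logistic(ga, y)
  expect_equal(f$intercept, log(1 / 3), tolerance = 1e-6)
  expect_equal(unname(f$beta), log(9), tolerance = 1e-6)
  expect_equal(unname(f$or), 9, tolerance = 1e-5)
  expect_equal(unname(f$group_prob), c(0.25, 0.75))
  # saturated log-likelihood in closed form
  ll_expected <- (1 * log(.25) + 3 * log(.75)) + (3 * log(.75) + 1 * log(.25))
  expect_equal(f$loglik, ll_expected, tolerance = 1e-8)

  # K = 0: intercept-only MLE is logit of the mean
  f0 <- fit_logistic(encode_groups(1:4, numeric()), c(1, 1, 0, 0))
  expect_equal(f0$intercept, 0, tolerance = 1e-8)
  expect_error(fit_logistic(ga, rep(0, 8)), "single value")
})

test_that("quasi-separated groups are flagged, not silently accepted", {
  ga <- encode_groups(c(1, 1, 1, 2, 2, 2), 1.5)
  f <- fit_logistic(ga, c(0, 0, 0, 1, 1, 1))
  expect_true(f$separation)
  expect_false(f$converged)
})

test_that("likelihood-ratio test clips noise and rejects nesting violations", {
  t0 <- lr_test(-10, -10, df = 1)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  expect_warning(tn <- lr_test(-10 - 1e-10, -10, df = 1), "clipped")
  expect_equal(tn$statistic, 0)
  expect_error(lr_test(-11, -10, df = 1), "negative")
  # saturated logistic example: statistic from closed-form log-likelihoods
  ga <- encode_groups(c(1, 1, 1, 1, 2, 2, 2, 2), 1.5)
  y <- c(1, 0, 0, 0, 1, 1, 1, 0)
  f <- fit_logistic(ga, y)
  full <- (log(.25) + 3 * log(.75)) + (3 * log(.75) + log(.25))
  null <- 8 * log(0.5)
  lt <- lr_test(f$loglik, f$loglik_null, df = 1)
  expect_equal(lt$statistic, 2 * (full - null), tolerance = 1e-8)
})

test_that("AUC is the Mann-Whitney probability with ties counting half", {
  expect_equal(compute_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(compute_auc(rep(7, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(compute_auc(c(1, 1, 2, 2), c(0, 0, 1, 1)), 1)
  expect_error(compute_auc(1:4, rep(1, 4)), "both outcome classes")
  # property: equals brute force on random instances with heavy ties
  set.seed(42)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    score <- sample(1:8, n, replace = TRUE)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(compute_auc(score, y), brute_auc(score, y), tolerance = 1e-12)
  }
})

test_that("Kaplan-Meier estimates match hand computation and empirical CDF", {
  km <- km_estimate(rep(0, 3), time = c(1, 2, 3), event = c(1, 0, 1))
  expect_equal(km$surv[km$time == 1], 2 / 3, tolerance = 1e-10)
  expect_equal(km$surv[km$time == 3], 0, tolerance = 1e-10)
  # no censoring: product-limit is 1 - empirical CDF
  set.seed(5)
  t <- rexp(40)
  km2 <- km_estimate(rep(1, 40), t, rep(1, 40))
  ecdf_surv <- 1 - ecdf(t)(km2$time)
  expect_equal(km2$surv, ecdf_surv, tolerance = 1e-10)
  expect_error(km_estimate(integer(), numeric(), numeric()), "empty")
})

test_that("Pearson chi-square matches the direct formula and chisq.test", {
  expect_equal(chi2_test(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(chi2_test(rbind(c(10, 10), c(10, 10)))$p, 1)
  expect_equal(chi2_test(rbind(c(30, 10), c(10, 30)))$statistic, 20)
  expect_error(chi2_test(rbind(c(0, 0), c(10, 30))), "degenerate")
  set.seed(9)
  for (i in 1:10) {
    tab <- matrix(rpois(6, 20) + 1, 3, 2)
    mine <- chi2_test(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
})

test_that("classification metrics collapse groups to a 2x2 prediction", {
  # groups with fitted probabilities 0.2 / 0.8 and outcomes matching exactly
  g <- rep(c(0, 1), each = 5)
  y <- c(1, 0, 0, 0, 0, 1, 1, 1, 1, 0)
  ga <- encode_groups(g, 0.5)
  f <- fit_logistic(ga, y)
  m <- classification_metrics(g, y, fit = f)
  expect_equal(m$sensitivity, 4 / 5)
  expect_equal(m$specificity, 4 / 5)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sens_plus_spec, 1.6)
  # perfect prediction
  mp <- classification_metrics(g, rep(c(0, 1), each = 5), prob = g)
  expect_equal(mp$sens_plus_spec, 2)
  expect_equal(mp$accuracy, 1)
  # top-group rule needs no fit
  mt <- classification_metrics(g, y, rule = "top")
  expect_equal(mt$sensitivity, 4 / 5)
  # one-sided prediction warns
  expect_warning(classification_metrics(g, y, prob = rep(0.9, 10)),
                 "degenerate prediction")
})
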