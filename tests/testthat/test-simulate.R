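# Synthetic-cohort generators: determinism, marginal behavior, and joint
# recovery of the generating parameters by the fitting engines.

test_that("identical seeds reproduce identical cohorts; configs validate", {
  cfg <- survival_sim_config(n = 300, true_cuts = c(20, 28),
                             group_hazards = c(0.1, 0.05, 0.2), seed = 42)
  a <- simulate_survival_cohort(cfg)
  b <- simulate_survival_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  cfgb <- binary_sim_config(n = 300, true_cuts = 24,
                            group_event_prob = c(0.2, 0.6), seed = 42)
  expect_identical(as.data.frame(simulate_binary_cohort(cfgb)),
                   as.data.frame(simulate_binary_cohort(cfgb)))
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_survival_cohort(cfg)); after <- runif(1)
  expect_identical(before, after)

  expect_error(survival_sim_config(100, c(20, 28), c(0.1, 0.2)), "length")
  expect_error(survival_sim_config(100, 20, c(0.1, -0.2)), "positive")
  expect_error(binary_sim_config(100, 20, c(0.5, 1)), "strictly in")
})

test_that("disabling censoring makes every subject an event", {
  cfg <- survival_sim_config(n = 200, true_cuts = 24,
                             group_hazards = c(0.1, 0.3),
                             censor_rate = 0, admin_censor_time = Inf,
                             seed = 7)
  co <- simulate_survival_cohort(cfg)
  expect_true(all(co$event == 1))
})

test_that("group event fractions concentrate on the generating probabilities", {
  cfg <- binary_sim_config(n = 6000, true_cuts = bmi_like_true_cuts,
                           group_event_prob = c(0.1, 0.4, 0.8),
                           z_dist = bmi_like_z_dist, seed = 11)
  co <- simulate_binary_cohort(cfg)
  frac <- tapply(co$y, co$true_group, mean)
  expect_true(all(abs(as.numeric(frac) - c(0.1, 0.4, 0.8)) < 0.03))
  # equal probabilities: the ordinal group score is uninformative (AUC ~ 0.5)
  cfg0 <- binary_sim_config(n = 2000, true_cuts = bmi_like_true_cuts,
                            group_event_prob = rep(0.5, 3),
                            z_dist = bmi_like_z_dist, seed = 12)
  co0 <- simulate_binary_cohort(cfg0)
  expect_lt(abs(compute_auc(co0$true_group, co0$y) - 0.5), 0.03)
})

test_that("fits on large simulations recover the generating log-odds/log-HR", {
  # logistic: saturated fit recovers group log-odds within 0.1 at n = 1e4
  probs <- c(0.15, 0.45, 0.75)
  cfgb <- binary_sim_config(n = 10000, true_cuts = bmi_like_true_cuts,
                            group_event_prob = probs,
                            z_dist = bmi_like_z_dist, seed = 21)
  cb <- simulate_binary_cohort(cfgb)
  fb <- fit_logistic(encode_groups(cb$z, bmi_like_true_cuts, "onehot"), cb$y)
  lo <- qlogis(probs)
  expect_lt(abs(fb$intercept - lo[1]), 0.1)
  expect_true(all(abs(fb$beta - (lo[2:3] - lo[1])) < 0.1))

  # Cox: exponential groups satisfy PH exactly with log-HR = log(h_g/h_0)
  hz <- c(0.05, 0.15, 0.45)
  cfgs <- survival_sim_config(n = 10000, true_cuts = bmi_like_true_cuts,
                              group_hazards = hz, z_dist = bmi_like_z_dist,
                              censor_rate = 0.1, seed = 22)
  cs <- simulate_survival_cohort(cfgs)
  fs <- fit_cox(encode_groups(cs$z, bmi_like_true_cuts, "onehot"),
                cs$time, cs$event)
  expect_true(all(abs(fs$beta - log(hz[2:3] / hz[1])) < 0.1))
})

test_that("preset scenarios produce cohorts of the documented shape", {
  ln <- simulate_scenario("lymph_nodes", n = 400, seed = 2)
  expect_equal(attr(ln, "spec")$mode, "survival")
  expect_true(all(ln$z == floor(ln$z)))  # counts
  st <- simulate_scenario("stromal", n = 400, seed = 2)
  expect_equal(attr(st, "spec")$mode, "binary")
  expect_true(all(st$z >= 0 & st$z <= 1))
  ts <- simulate_scenario("tumor_size", n = 400, seed = 2)
  expect_true(all(ts$z > 0))
  bmi <- simulate_scenario("bmi", n = 400, seed = 2, with_covariates = TRUE)
  expect_true(all(c("age", "stage", "histology") %in% names(bmi)))
})
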