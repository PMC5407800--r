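# Small seeded cohorts shared across tests. z is rounded to whole units so
# the candidate grid stays compact (<= ~40 distinct values at n = 150).

make_surv_cohort <- function(seed, n = 150, hazards = c(0.15, 0.05, 0.2),
                             cuts = c(20, 28)) {
  cfg <- survival_sim_config(n = n, true_cuts = cuts, group_hazards = hazards,
                             censor_rate = 0.1, seed = seed)
  co <- simulate_survival_cohort(cfg)
  co$z <- round(co$z)
  as_cohort(as.data.frame(co), attr(co, "spec"))
}

make_bin_cohort <- function(seed, n = 150, probs = c(0.15, 0.4, 0.7),
                            cuts = c(20, 28)) {
  cfg <- binary_sim_config(n = n, true_cuts = cuts, group_event_prob = probs,
                           seed = seed)
  co <- simulate_binary_cohort(cfg)
  co$z <- round(co$z)
  as_cohort(as.data.frame(co), attr(co, "spec"))
}

bmi_like_z_dist <- list(dist = "lognormal", meanlog = log(24.25), sdlog = 0.16)

bmi_like_true_cuts <- exp(log(24.25) + stats::qnorm(c(1 / 3, 2 / 3)) * 0.16)
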