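# Seeded synthetic-cohort generators with known true cutpoints.
#
# Event times are exponential within each latent risk group, so the
# proportional-hazards assumption holds exactly and the true adjacent-group
# log hazard ratios are ln(h_{g+1}/h_g) analytically; binary outcomes are
# Bernoulli with a per-group event probability (a step function of the risk
# factor on the log-odds scale). This makes parameter-recovery checks sharp.

# Sample n risk-factor values from a distribution spec.
sample_z <- function(n, z_dist) {
  d <- z_dist$dist %||% "lognormal"
  zz <- switch(
    d,
    lognormal = stats::rlnorm(n, z_dist$meanlog %||% log(24), z_dist$sdlog %||% 0.2),
    normal = stats::rnorm(n, z_dist$mean %||% 0, z_dist$sd %||% 1),
    uniform = stats::runif(n, z_dist$min %||% 0, z_dist$max %||% 1),
    nbinom = stats::rnbinom(n, size = z_dist$size %||% 1.2, mu = z_dist$mu %||% 2),
    beta = stats::rbeta(n, z_dist$shape1 %||% 2, z_dist$shape2 %||% 2),
    stop("unknown z distribution: ", d, call. = FALSE)
  )
  pm <- z_dist$point_mass
  if (!is.null(pm)) {
    hit <- stats::runif(n) < pm$p
    zz[hit] <- pm$at
  }
  zz
}

#' Configuration for a synthetic survival cohort
#'
#' Defines a cohort whose hazard is piecewise constant across latent risk
#' groups given by known true cutpoints: `z` is drawn from `z_dist`, the
#' group is `encode_groups(z, true_cuts)`, the event time is exponential
#' with the group's hazard, and follow-up is right-censored by an independent
#' exponential censoring time truncated at an administrative horizon.
#'
#' @param n cohort size.
#' @param true_cuts numeric vector of true cutpoints (strictly increasing).
#' @param group_hazards constant hazard per group, events/year
#'   (length `length(true_cuts) + 1`, all > 0).
#' @param z_dist risk-factor distribution spec: a list with `dist` in
#'   `"lognormal"`, `"normal"`, `"uniform"`, `"nbinom"`, `"beta"` plus its
#'   parameters, optionally `point_mass = list(at=, p=)`.
#' @param censor_rate exponential censoring hazard (per year; 0 disables
#'   random censoring).
#' @param admin_censor_time administrative maximum follow-up (years;
#'   `Inf` disables).
#' @param with_covariates if `TRUE`, add adjustment covariates `age`
#'   (years), `stage` (early/late) and `histology` (squamous/adeno/other)
#'   with modest multiplicative hazard effects.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A `survival_sim_config` list.
#' @export
survival_sim_config <- function(n, true_cuts, group_hazards,
                                z_dist = list(dist = "lognormal",
                                              meanlog = log(24), sdlog = 0.2),
                                censor_rate = 0.15,
                                admin_censor_time = 22,
                                with_covariates = FALSE,
                                seed = 1) {
  true_cuts <- unclass(cutpoint_set(true_cuts))
  if (length(group_hazards) != length(true_cuts) + 1L) {
    stop("`group_hazards` must have length(true_cuts) + 1 entries", call. = FALSE)
  }
  if (any(group_hazards <= 0)) stop("hazards must be positive", call. = FALSE)
  if (censor_rate < 0 || n < 1) stop("invalid simulation config", call. = FALSE)
  structure(list(n = as.integer(n), true_cuts = true_cuts,
                 group_hazards = group_hazards, z_dist = z_dist,
                 censor_rate = censor_rate,
                 admin_censor_time = admin_censor_time,
                 with_covariates = isTRUE(with_covariates),
                 seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Configuration for a synthetic binary-outcome cohort
#'
#' @inheritParams survival_sim_config
#' @param group_event_prob event probability per group, strictly inside
#'   (0, 1), length `length(true_cuts) + 1`.
#' @return A `binary_sim_config` list.
#' @export
binary_sim_config <- function(n, true_cuts, group_event_prob,
                              z_dist = list(dist = "lognormal",
                                            meanlog = log(24), sdlog = 0.2),
                              with_covariates = FALSE,
                              seed = 1) {
  true_cuts <- unclass(cutpoint_set(true_cuts))
  if (length(group_event_prob) != length(true_cuts) + 1L) {
    stop("`group_event_prob` must have length(true_cuts) + 1 entries",
         call. = FALSE)
  }
  if (any(group_event_prob <= 0 | group_event_prob >= 1)) {
    stop("group event probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  if (n < 1) stop("invalid simulation config", call. = FALSE)
  structure(list(n = as.integer(n), true_cuts = true_cuts,
                 group_event_prob = group_event_prob, z_dist = z_dist,
                 with_covariates = isTRUE(with_covariates),
                 seed = as.integer(seed)),
            class = "binary_sim_config")
}

sim_covariates <- function(n) {
  data.frame(
    age = round(stats::rnorm(n, 55, 12), 1),
    stage = sample(c("early", "late"), n, TRUE, prob = c(0.82, 0.18)),
    histology = sample(c("squamous", "adeno", "other"), n, TRUE,
                       prob = c(0.72, 0.14, 0.14)),
    stringsAsFactors = FALSE)
}

# log-hazard / log-odds shifts applied when covariates are simulated
cov_effects <- list(age = 0.02, stage_late = 0.9,
                    histology_adeno = 0.3, histology_other = 0.5)

cov_linear_predictor <- function(cv) {
  cov_effects$age * (cv$age - 55) +
    cov_effects$stage_late * (cv$stage == "late") +
    cov_effects$histology_adeno * (cv$histology == "adeno") +
    cov_effects$histology_other * (cv$histology == "other")
}

#' Simulate a survival cohort with known true cutpoints
#'
#' @param cfg a [survival_sim_config()].
#' @return A `cohort` data frame with columns `id`, `z`, `time`, `event`,
#'   `true_group` (and covariates if configured), carrying a matching
#'   [outcome_spec()].
#' @examples
#' cfg <- survival_sim_config(n = 100, true_cuts = 25,
#'                            group_hazards = c(0.05, 0.2), seed = 3)
#' cohort <- simulate_survival_cohort(cfg)
#' @export
simulate_survival_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "survival_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n
    z <- sample_z(n, cfg$z_dist)
    group <- encode_groups(z, cfg$true_cuts)$group
    rate <- cfg$group_hazards[group + 1L]
    cv <- if (cfg$with_covariates) sim_covariates(n) else NULL
    if (!is.null(cv)) rate <- rate * exp(cov_linear_predictor(cv))
    t_event <- stats::rexp(n, rate)
    t_cens <- if (cfg$censor_rate > 0) stats::rexp(n, cfg$censor_rate) else
      rep(Inf, n)
    t_cens <- pmin(t_cens, cfg$admin_censor_time)
    time <- pmin(t_event, t_cens)
    dat <- data.frame(id = sprintf("s%04d", seq_len(n)), z = z,
                      time = time, event = as.integer(t_event <= t_cens),
                      true_group = group)
    if (!is.null(cv)) dat <- cbind(dat, cv)
    spec <- outcome_spec("survival", z = "z", time = "time", event = "event",
                         covariates = if (is.null(cv)) character() else
                           names(cv), id = "id")
    as_cohort(dat, spec)
  })
}

#' Simulate a binary-outcome cohort with known true cutpoints
#'
#' @param cfg a [binary_sim_config()].
#' @return A `cohort` data frame with columns `id`, `z`, `y`, `true_group`
#'   (and covariates if configured).
#' @export
simulate_binary_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "binary_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n
    z <- sample_z(n, cfg$z_dist)
    group <- encode_groups(z, cfg$true_cuts)$group
    p <- cfg$group_event_prob[group + 1L]
    cv <- if (cfg$with_covariates) sim_covariates(n) else NULL
    if (!is.null(cv)) p <- stats::plogis(stats::qlogis(p) + cov_linear_predictor(cv))
    dat <- data.frame(id = sprintf("s%04d", seq_len(n)), z = z,
                      y = stats::rbinom(n, 1L, p), true_group = group)
    if (!is.null(cv)) dat <- cbind(dat, cv)
    spec <- outcome_spec("binary", z = "z", y = "y",
                         covariates = if (is.null(cv)) character() else
                           names(cv), id = "id")
    as_cohort(dat, spec)
  })
}

#' Preset simulation scenarios
#'
#' Four ready-made scenarios emulating typical clinical analyses of a
#' cervical-cancer-like cohort, with defaults chosen to be realistic for
#' each risk factor:
#' \describe{
#'   \item{`lymph_nodes`}{discrete metastatic lymph-node count
#'     (overdispersed, mostly 0), survival outcome, one true cut at 5 nodes,
#'     hazards 0.04 vs 0.25 events/year.}
#'   \item{`tumor_size`}{tumor diameter in cm (lognormal, median 3.5),
#'     binary nodal-metastasis outcome, one true cut at 3.25 cm, event
#'     probabilities 0.12 vs 0.45.}
#'   \item{`bmi`}{body-mass index (lognormal, median about 24), survival
#'     outcome, two true cuts at 19.88 and 29.59 with U-shaped risk:
#'     hazards 0.10, 0.03, 0.10 events/year.}
#'   \item{`stromal`}{stromal-invasion fraction in `[0, 1]` (beta with a
#'     point mass at full penetration), binary lymphovascular-invasion
#'     outcome, two true cuts at 0.32 and 0.97, event probabilities
#'     0.08, 0.30, 0.77.}
#' }
#'
#' @param scenario one of `"lymph_nodes"`, `"tumor_size"`, `"bmi"`,
#'   `"stromal"`.
#' @param n cohort size (default 797).
#' @param seed integer seed.
#' @param with_covariates add adjustment covariates (see
#'   [survival_sim_config()]).
#' @return A `survival_sim_config` or `binary_sim_config`.
#' @export
scenario_config <- function(scenario = c("lymph_nodes", "tumor_size",
                                         "bmi", "stromal"),
                            n = 797, seed = 1, with_covariates = FALSE) {
  scenario <- match.arg(scenario)
  switch(
    scenario,
    lymph_nodes = survival_sim_config(
      n = n, true_cuts = 5, group_hazards = c(0.04, 0.25),
      z_dist = list(dist = "nbinom", size = 0.9, mu = 2.5),
      censor_rate = 0.12, admin_censor_time = 22,
      with_covariates = with_covariates, seed = seed),
    tumor_size = binary_sim_config(
      n = n, true_cuts = 3.25, group_event_prob = c(0.12, 0.45),
      z_dist = list(dist = "lognormal", meanlog = log(3.5), sdlog = 0.45),
      with_covariates = with_covariates, seed = seed),
    bmi = survival_sim_config(
      n = n, true_cuts = c(19.88, 29.59), group_hazards = c(0.10, 0.03, 0.10),
      z_dist = list(dist = "lognormal", meanlog = log(24.25), sdlog = 0.16),
      censor_rate = 0.15, admin_censor_time = 22,
      with_covariates = with_covariates, seed = seed),
    stromal = binary_sim_config(
      n = n, true_cuts = c(0.32, 0.97), group_event_prob = c(0.08, 0.30, 0.77),
      z_dist = list(dist = "beta", shape1 = 1.6, shape2 = 1.4,
                    point_mass = list(at = 1, p = 0.06)),
      with_covariates = with_covariates, seed = seed)
  )
}

#' Simulate a preset scenario cohort
#'
#' Convenience wrapper: builds the [scenario_config()] and simulates it.
#'
#' @inheritParams scenario_config
#' @return A `cohort` data frame.
#' @export
simulate_scenario <- function(scenario, n = 797, seed = 1,
                              with_covariates = FALSE) {
  cfg <- scenario_config(scenario, n = n, seed = seed,
                         with_covariates = with_covariates)
  if (inherits(cfg, "survival_sim_config")) simulate_survival_cohort(cfg)
  else simulate_binary_cohort(cfg)
}
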