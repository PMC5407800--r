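# Model-fitting engines for categorized risk factors. Cox partial-likelihood
# and logistic maximum-likelihood fits delegate to survival::coxph (Efron tie
# handling) and stats::glm; the surrounding code standardizes inputs, guards
# degenerate data, and extracts the quantities the cutpoint machinery needs
# (log-likelihoods, per-coefficient HR/OR, convergence flags).

#' Fit a Cox proportional-hazards model to categorized risk groups
#'
#' Fits `h(t | Z*) = h0(t) exp(sum_k beta_k Z_k)` by maximizing the partial
#' likelihood (Efron approximation for tied event times), where the `Z_k` are
#' the dummy variables of a [encode_groups()] assignment, optionally plus
#' adjustment covariates.
#'
#' @param assign a `group_assignment` from [encode_groups()].
#' @param time,event follow-up times and 0/1 event indicators.
#' @param extra_covariates optional data frame or numeric matrix of
#'   adjustment covariates (aligned with `time`).
#' @param baseline if `TRUE`, also return the Breslow cumulative baseline
#'   hazard (for plotting only; the partial likelihood profiles it out).
#' @return An object of class `cox_fit`: coefficients `beta`, `se`, hazard
#'   ratios `hr` with 95% CI, `loglik`, `loglik_null`, `df`, `converged`,
#'   and optionally `baseline`.
#' @export
fit_cox <- function(assign, time, event, extra_covariates = NULL,
                    baseline = FALSE) {
  stopifnot(inherits(assign, "group_assignment"))
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (sum(event) < 1) stop("degenerate data: no events observed", call. = FALSE)
  X <- assign$dummies
  if (ncol(X) > 0L && length(unique(assign$group)) < 2L) {
    stop("degenerate data: fewer than 2 non-empty groups", call. = FALSE)
  }
  if (!is.null(extra_covariates)) {
    mm <- stats::model.matrix(~ ., data = as.data.frame(extra_covariates))[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  if (ncol(X) == 0L) {
    fit <- survival::coxph(survival::Surv(time, event) ~ 1, ties = "efron")
    ll <- fit$loglik[1L]
    out <- structure(list(beta = numeric(0), se = numeric(0), hr = numeric(0),
                          ci_low = numeric(0), ci_high = numeric(0),
                          loglik = ll, loglik_null = ll, df = 0L,
                          converged = TRUE, n = length(time),
                          n_event = sum(event)),
                     class = "cox_fit")
    if (baseline) out$baseline <- survival::basehaz(fit, centered = FALSE)
    return(out)
  }
  dat <- data.frame(.time = time, .event = event, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  converged <- !warned && all(is.finite(beta)) && all(abs(beta) < 15)
  out <- structure(
    list(beta = beta, se = se, hr = exp(beta),
         ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
         loglik = fit$loglik[2L], loglik_null = fit$loglik[1L],
         df = length(beta), converged = converged,
         n = length(time), n_event = sum(event)),
    class = "cox_fit")
  if (baseline) out$baseline <- survival::basehaz(fit, centered = FALSE)
  out
}

#' Fit a logistic regression to categorized risk groups
#'
#' Fits `logit p(Y = 1 | Z*) = alpha + sum_k beta_k Z_k` by maximum
#' likelihood (IRLS), with group 0 as the reference. Without adjustment
#' covariates the model is saturated in the groups, so the fitted group
#' probabilities equal the observed group event fractions. A group whose
#' outcomes are all 0 or all 1 makes the MLE diverge (quasi-separation);
#' the fit is returned with `separation = TRUE` and `converged = FALSE`
#' so that searches can reject the candidate split.
#'
#' @inheritParams fit_cox
#' @param y 0/1 outcome vector.
#' @return An object of class `logistic_fit`: `intercept`, `beta`, `se`,
#'   odds ratios `or` with 95% CI, `loglik`, `loglik_null`, `df` (number of
#'   non-intercept coefficients), `group_prob` (fitted probability per group,
#'   unadjusted fits only), `converged`, `separation`.
#' @examples
#' ga <- encode_groups(c(1, 1, 1, 1, 2, 2, 2, 2), cuts = 2)
#' f <- fit_logistic(ga, y = c(1, 0, 0, 0, 1, 1, 1, 0))
#' c(f$intercept, f$beta)  # log(1/3), log(9)
#' @export
fit_logistic <- function(assign, y, extra_covariates = NULL) {
  stopifnot(inherits(assign, "group_assignment"))
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("degenerate data: outcome takes a single value", call. = FALSE)
  }
  X <- assign$dummies
  if (!is.null(extra_covariates)) {
    mm <- stats::model.matrix(~ ., data = as.data.frame(extra_covariates))[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fml <- if (ncol(X) == 0L) .y ~ 1 else
    stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(X)),
                                          collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = dat))
  cf <- stats::coef(fit)
  beta <- cf[-1L]
  se <- sqrt(diag(stats::vcov(fit)))[-1L]
  ll <- as.numeric(stats::logLik(fit))
  n1 <- sum(y); n <- length(y)
  ll_null <- n1 * log(n1 / n) + (n - n1) * log(1 - n1 / n)
  # group-level separation check (unadjusted path)
  separation <- FALSE
  group_prob <- NULL
  if (is.null(extra_covariates)) {
    frac <- tapply(y, assign$group, mean)
    group_prob <- stats::setNames(as.numeric(frac), names(frac))
    separation <- assign$K > 0L && any(frac %in% c(0, 1))
  } else {
    separation <- any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)
  }
  structure(
    list(intercept = unname(cf[1L]), beta = beta,
         se = se, or = exp(beta),
         ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
         loglik = ll, loglik_null = ll_null, df = length(beta),
         group_prob = group_prob, fitted = fit$fitted.values,
         converged = fit$converged && !separation, separation = separation,
         n = n, n_event = n1),
    class = "logistic_fit")
}

#' Likelihood-ratio test between nested fits
#'
#' `statistic = 2 (loglik_full - loglik_null)` referred to a chi-square
#' distribution. A tiny negative statistic (numerical noise below 1e-8) is
#' clipped to zero with a warning; a larger one signals a violated nesting
#' (a failed fit) and raises an error.
#'
#' @param full_loglik,null_loglik maximized log-likelihoods of the full and
#'   null models.
#' @param df number of extra parameters in the full model.
#' @param method label for the result (`"cox_lrt"` or `"logistic_lrt"`).
#' @return A `cut_test` result.
#' @export
lr_test <- function(full_loglik, null_loglik, df, method = "lrt") {
  stopifnot(df >= 1)
  stat <- 2 * (full_loglik - null_loglik)
  if (stat < -1e-8) {
    stop("likelihood-ratio statistic is negative (", format(stat),
         "): nested fit failed", call. = FALSE)
  }
  if (stat < 0) {
    warning("negative LRT statistic within numerical noise; clipped to 0")
    stat <- 0
  }
  cut_test(stat, df, method = method)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC is computed as the Mann-Whitney probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties counting 1/2 —
#' identical to trapezoidal integration of the empirical ROC curve. Constant
#' scores give exactly 0.5.
#'
#' @param score numeric risk scores (higher = more likely positive).
#' @param y 0/1 outcome labels.
#' @return AUC in `[0, 1]`.
#' @examples
#' compute_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))  # 0.75
#' @export
compute_auc <- function(score, y) {
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("degenerate data: both outcome classes required for AUC", call. = FALSE)
  }
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Kaplan-Meier survival curves per risk group
#'
#' Product-limit estimates of the survivor function within each risk group.
#' Empty groups are dropped with a warning.
#'
#' @inheritParams logrank_test
#' @return An object of class `km_curves`: a data frame with columns
#'   `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(group, time, event) {
  if (length(time) == 0L) stop("empty input", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  g <- factor(group)
  if (any(table(g) == 0L)) {
    warning("dropping empty group level(s)")
    g <- droplevels(g)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  if (length(levels(g)) == 1L) {
    grp <- rep(levels(g), length(fit$time))
  } else {
    grp <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  structure(
    data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, surv = fit$surv,
               stringsAsFactors = FALSE),
    class = c("km_curves", "data.frame"))
}

#' Pearson chi-square test of a groups-by-outcome contingency table
#'
#' `sum (O - E)^2 / E` without continuity correction,
#' `df = (rows - 1)(cols - 1)`. A table with a zero expected count (an empty
#' row or column margin) is degenerate and raises an error.
#'
#' @param table matrix of non-negative counts (risk groups in rows, outcome
#'   classes in columns).
#' @return A `cut_test` result.
#' @examples
#' chi2_test(rbind(c(30, 10), c(10, 30)))$statistic  # 20
#' @export
chi2_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("contingency table needs at least 2 rows and 2 columns", call. = FALSE)
  }
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(E == 0)) {
    stop("degenerate table: zero expected count (empty margin)", call. = FALSE)
  }
  stat <- sum((table - E)^2 / E)
  cut_test(stat, (nrow(table) - 1L) * (ncol(table) - 1L), method = "chi2")
}

#' Classification metrics for a categorized risk factor
#'
#' Collapses the K + 1 risk groups to a binary prediction and reports
#' sensitivity, specificity, their sum (the Youden-style summary), and
#' accuracy on the induced 2x2 table. With the default rule a subject is
#' predicted positive iff the fitted event probability of its group is at
#' least 0.5; the alternative rule predicts positive only for the top risk
#' group.
#'
#' @param group ordinal group labels (0..K).
#' @param y 0/1 outcomes.
#' @param fit a `logistic_fit` providing per-group fitted probabilities
#'   (required for `rule = "prob"` unless `prob` is given).
#' @param prob optional per-subject predicted event probability, overriding
#'   `fit`.
#' @param rule `"prob"` (threshold fitted probability at 0.5, default) or
#'   `"top"` (top group vs the rest).
#' @return A list with `sensitivity`, `specificity`, `sens_plus_spec`,
#'   `accuracy`, and the 2x2 `table`; a degenerate one-sided prediction is
#'   flagged with a warning.
#' @export
classification_metrics <- function(group, y, fit = NULL, prob = NULL,
                                   rule = c("prob", "top")) {
  rule <- match.arg(rule)
  if (!all(y %in% c(0, 1))) stop("y must be 0/1", call. = FALSE)
  if (rule == "prob") {
    if (is.null(prob)) {
      if (is.null(fit) || is.null(fit$group_prob)) {
        stop("`rule = \"prob\"` needs a logistic fit with group probabilities ",
             "or an explicit `prob` vector", call. = FALSE)
      }
      prob <- fit$group_prob[as.character(group)]
    }
    pred <- as.integer(prob >= 0.5)
  } else {
    pred <- as.integer(group == max(group))
  }
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  if (length(unique(pred)) == 1L) {
    warning("degenerate prediction: all subjects predicted one class")
  }
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       sens_plus_spec = sens + spec,
       accuracy = (tp + tn) / length(y),
       table = matrix(c(tn, fn, fp, tp), 2L, 2L,
                      dimnames = list(pred = c("0", "1"), y = c("0", "1"))))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit on", x$n, "subjects (", x$n_event, "events ),",
      x$df, "coefficient(s);",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (x$df > 0L) {
    print(data.frame(beta = x$beta, se = x$se, HR = x$hr,
                     ci_low = x$ci_low, ci_high = x$ci_high))
  }
  cat(sprintf("loglik: %.4f (null %.4f)\n", x$loglik, x$loglik_null))
  invisible(x)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit on", x$n, "subjects (", x$n_event, "cases ),",
      x$df, "coefficient(s);",
      if (x$converged) "converged" else "NOT converged",
      if (x$separation) "[quasi-separation]" else "", "\n")
  cat(sprintf("intercept: %.4f\n", x$intercept))
  if (x$df > 0L) {
    print(data.frame(beta = x$beta, se = x$se, OR = x$or,
                     ci_low = x$ci_low, ci_high = x$ci_high))
  }
  cat(sprintf("loglik: %.4f (null %.4f)\n", x$loglik, x$loglik_null))
  invisible(x)
}
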