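#' Hold-out validation of discovered cutpoints
#'
#' Refits the categorized risk factor on an independent (testing) cohort,
#' entering the discovered cuts as a categorical factor (group 0, the lowest
#' risk group, as reference) together with adjustment covariates such as
#' age, stage, and histology. Categorical covariates are coded with their
#' most frequent level as reference. Survival cohorts are fitted with a Cox
#' proportional-hazards model (hazard ratios), binary cohorts with logistic
#' regression (odds ratios).
#'
#' @param cohort a `cohort` data frame (typically the held-out test part of
#'   [split_cohort()]).
#' @param cuts cutpoints discovered on the training cohort.
#' @param covariates character vector of adjustment-covariate column names;
#'   defaults to the covariates declared in the cohort's [outcome_spec()].
#' @return An object of class `holdout_validation`: a coefficient table
#'   (`term`, `estimate` = HR or OR, `ci_low`, `ci_high`, `p`), the model
#'   log-likelihoods, and the global likelihood-ratio test of the full model.
#' @export
validate_holdout <- function(cohort, cuts, covariates = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  cv <- cohort_vectors(cohort)
  spec <- cv$spec
  covariates <- covariates %||% spec$covariates
  missing_cov <- setdiff(covariates, names(cohort))
  if (length(missing_cov)) {
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  cuts <- unclass(cutpoint_set(cuts))
  ga <- encode_groups(cv$z, cuts, coding = "onehot")
  extra <- NULL
  if (length(covariates)) {
    extra <- as.data.frame(cohort)[, covariates, drop = FALSE]
    for (cl in covariates) {
      if (!is.numeric(extra[[cl]])) {
        f <- factor(extra[[cl]])
        ref <- names(which.max(table(f)))
        extra[[cl]] <- stats::relevel(f, ref = ref)
      }
    }
  }
  if (cv$mode == "survival") {
    fit <- fit_cox(ga, cv$time, cv$event, extra_covariates = extra)
    label <- "HR"
  } else {
    fit <- fit_logistic(ga, cv$y, extra_covariates = extra)
    label <- "OR"
  }
  wald_p <- 2 * stats::pnorm(-abs(fit$beta / fit$se))
  tab <- data.frame(term = names(fit$beta), estimate = exp(fit$beta),
                    ci_low = fit$ci_low, ci_high = fit$ci_high,
                    p = wald_p, row.names = NULL)
  global <- lr_test(fit$loglik, fit$loglik_null, df = max(1L, fit$df),
                    method = if (cv$mode == "survival") "cox_lrt" else
                      "logistic_lrt")
  structure(list(mode = cv$mode, estimate_label = label, cuts = cuts,
                 coefficients = tab, fit = fit, global_test = global,
                 n = fit$n, n_event = fit$n_event),
            class = "holdout_validation")
}

#' @export
print.holdout_validation <- function(x, ...) {
  cat("Hold-out validation (", x$mode, "), cuts at",
      paste(format(x$cuts), collapse = ", "), "\n")
  cat("n =", x$n, "; events/cases =", x$n_event, "\n")
  tab <- x$coefficients
  names(tab)[names(tab) == "estimate"] <- x$estimate_label
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("Global LRT: statistic = %.3f (df = %d), p = %.4g\n",
              x$global_test$statistic, x$global_test$df, x$global_test$p))
  invisible(x)
}
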