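#' Choose the optimal number of cutpoints by AIC
#'
#' For each candidate number of cutpoints K, the model categorizing the risk
#' factor into K + 1 groups is fitted and scored by
#' `AIC = 2 * n_params - 2 * loglik`: a Cox proportional-hazards model
#' (survival outcomes; parameter count K) or a logistic regression (binary
#' outcomes; parameter count K + 1 for the intercept). As K grows the
#' categorized model gains flexibility but also parameters; minimizing AIC
#' selects the optimal K. K = 0 (no split; the null model) is included as a
#' sanity floor by default. AIC ties go to the smaller K (parsimony).
#'
#' With the default `cuts_method = "quantile"` each K is scored at the
#' equally-spaced quantile cuts (the k/(K+1) quantiles of the risk factor),
#' so the number of groups is chosen *before* — and independently of — the
#' location search, matching a workflow that decides the number first and
#' locates the cuts afterwards. The alternative `cuts_method = "optimal"`
#' scores each K at its criterion-optimal cuts from [search_cutpoints()];
#' because the searched maximal statistic inflates with K (the optimism of
#' minimal-p selection, which this package deliberately does not correct),
#' that variant systematically over-selects larger K when the risk factor
#' carries no signal, and is provided for comparison only.
#'
#' @param cohort a `cohort` data frame.
#' @param K_range integer vector of candidate cutpoint counts (default 0:2).
#' @param cuts_method `"quantile"` (default) or `"optimal"`; see Details.
#' @param criterion location criterion passed to [search_cutpoints()] when
#'   `cuts_method = "optimal"`; defaults to `"logrank"` (survival) or
#'   `"logistic_lrt"` (binary).
#' @param grid optional [candidate_cutpoints()] grid shared across K.
#' @return An object of class `aic_profile`: a data frame with one row per K
#'   (`K`, `loglik`, `n_params`, `aic`, `delta_aic`, `cuts`) and attribute
#'   `best_K`.
#' @examples
#' \donttest{
#' cfg <- scenario_config("stromal", n = 400, seed = 7)
#' cohort <- simulate_binary_cohort(cfg)
#' prof <- find_cut_number(cohort, K_range = 0:2)
#' attr(prof, "best_K")
#' }
#' @export
find_cut_number <- function(cohort, K_range = 0:2,
                            cuts_method = c("quantile", "optimal"),
                            criterion = NULL, grid = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  cuts_method <- match.arg(cuts_method)
  if (length(K_range) == 0L) stop("`K_range` is empty", call. = FALSE)
  K_range <- sort(unique(as.integer(K_range)))
  cv <- cohort_vectors(cohort)
  if (is.null(grid) && cuts_method == "optimal") {
    grid <- candidate_cutpoints(cv$z)
  }
  rows <- list()
  for (K in K_range) {
    entry <- tryCatch({
      if (K == 0L) {
        cuts <- numeric(0)
      } else if (cuts_method == "quantile") {
        cuts <- stats::quantile(cv$z, seq_len(K) / (K + 1L), names = FALSE)
        if (any(diff(c(-Inf, cuts)) <= 0) || min(cuts) <= min(cv$z) ||
            max(cuts) > max(cv$z)) {
          stop("quantile cuts are not strictly increasing interior values")
        }
      } else {
        cuts <- as.numeric(search_cutpoints(cohort, K, criterion = criterion,
                                            grid = grid)$best)
      }
      ga <- encode_groups(cv$z, cuts)
      if (cv$mode == "survival") {
        fit <- fit_cox(ga, cv$time, cv$event)
        n_params <- K
      } else {
        fit <- fit_logistic(ga, cv$y)
        n_params <- K + 1L
      }
      data.frame(K = K, loglik = fit$loglik, n_params = n_params,
                 aic = 2 * n_params - 2 * fit$loglik,
                 cuts = I(list(cuts)))
    }, error = function(e) {
      warning("K = ", K, " infeasible and omitted: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(entry)) rows[[length(rows) + 1L]] <- entry
  }
  if (length(rows) == 0L) {
    stop("no feasible number of cutpoints in `K_range`", call. = FALSE)
  }
  prof <- do.call(rbind, rows)
  prof$delta_aic <- prof$aic - min(prof$aic)
  best_K <- prof$K[which.min(prof$aic)]  # ties resolve to the smaller K
  structure(prof, best_K = best_K, mode = cv$mode,
            class = c("aic_profile", "data.frame"))
}

#' Rank an AIC profile
#'
#' Orders the candidate cutpoint counts of an `aic_profile` by AIC and
#' reports the difference from the minimum, the standard human-readable
#' model-comparison summary.
#'
#' @param profile an `aic_profile` from [find_cut_number()].
#' @return A data frame ordered by AIC (ties toward smaller K), with a
#'   `delta_aic` column; the chosen K is in attribute `best_K`.
#' @export
compare_aic <- function(profile) {
  stopifnot(inherits(profile, "aic_profile"))
  out <- as.data.frame(profile)
  out <- out[order(out$aic, out$K), , drop = FALSE]
  out$delta_aic <- out$aic - min(out$aic)
  rownames(out) <- NULL
  structure(out, best_K = out$K[1L])
}

#' @export
print.aic_profile <- function(x, ...) {
  cat("AIC profile (", attr(x, "mode"), " outcome); best K =",
      attr(x, "best_K"), "\n")
  df <- as.data.frame(x)
  df$cuts <- vapply(df$cuts, function(cc)
    if (length(cc)) paste(format(cc), collapse = ", ") else "-", character(1))
  print(df, row.names = FALSE)
  invisible(x)
}
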