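# Exhaustive cutpoint-location search.
#
# The search evaluates every strictly increasing K-tuple of candidate
# cutpoints whose induced K+1 groups satisfy minimum size (and, in survival
# mode, minimum event-count) constraints, and returns the tuple maximizing
# the chosen criterion (equivalently, minimizing its p-value at fixed df).
#
# Because every tuple is a pair of thresholds on the same cohort, the per-
# tuple statistics are computed from quantities precomputed once per
# threshold ("risk-set tables precomputed once"):
#   survival: per-threshold observed-minus-expected sums a_c, variance pieces
#     u_c and the cross matrix M[c,c'] = sum_t w_t R_ct R_c't / N_t^2, from
#     which the 1- and 2-cut log-rank statistics are closed forms;
#   binary: per-threshold case and subject counts, from which the saturated
#     logistic LRT, Pearson chi-square, and grouped AUC are closed forms.
# These engines are cross-checked in the test suite against survdiff, glm,
# chisq.test, and brute-force pairwise AUC.

# --- survival threshold tables -------------------------------------------

threshold_surv_tables <- function(z, time, event, cand) {
  m <- length(cand)
  dtimes <- sort(unique(time[event == 1]))
  tt <- length(dtimes)
  zbin <- findInterval(z, cand)            # 0..m; bin >= k  <=>  z >= cand[k]
  last_risk <- findInterval(time, dtimes)  # at risk for event times 1..last_risk
  # per-bin at-risk and event counts over event times
  bin_f <- factor(zbin, levels = 0:m)
  sel <- last_risk > 0L
  cnt <- table(bin_f[sel], factor(last_risk[sel], levels = seq_len(tt)))
  cnt <- matrix(as.numeric(cnt), m + 1L, tt)
  atrisk_bin <- t(apply(cnt, 1L, function(r) rev(cumsum(rev(r)))))
  if (tt == 1L) atrisk_bin <- matrix(atrisk_bin, m + 1L, tt)
  ev <- event == 1
  evt_bin <- table(bin_f[ev], factor(match(time[ev], dtimes), levels = seq_len(tt)))
  evt_bin <- matrix(as.numeric(evt_bin), m + 1L, tt)
  # threshold rows: candidate k aggregates bins k..m (z >= cand[k])
  rcum <- function(mat) {
    out <- apply(mat[rev(seq_len(nrow(mat))), , drop = FALSE], 2L, cumsum)
    out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
    out[-1L, , drop = FALSE]  # drop bin-0 row; rows 1..m are the thresholds
  }
  R <- rcum(atrisk_bin)
  Dm <- rcum(evt_bin)
  N <- colSums(atrisk_bin)
  d <- colSums(evt_bin)
  w <- ifelse(N > 1, d * (N - d) / (N - 1), 0)
  a <- rowSums(Dm) - as.vector(R %*% (d / N))
  u <- as.vector(R %*% (w / N))
  M <- tcrossprod(sweep(R, 2L, sqrt(w) / N, "*"))
  zb <- tabulate(zbin + 1L, nbins = m + 1L)
  size <- rev(cumsum(rev(zb)))[-1L]        # subjects with z >= cand[k]
  eb <- tabulate(zbin[ev] + 1L, nbins = m + 1L)
  events_thr <- rev(cumsum(rev(eb)))[-1L]
  list(a = a, u = u, M = M, size = size, events = events_thr,
       n = length(z), n_events = sum(event))
}

# --- binary threshold tables ---------------------------------------------

threshold_bin_tables <- function(z, y, cand) {
  m <- length(cand)
  zbin <- findInterval(z, cand)
  tot_b <- tabulate(zbin + 1L, nbins = m + 1L)
  pos_b <- tabulate(zbin[y == 1] + 1L, nbins = m + 1L)
  list(tot = rev(cumsum(rev(tot_b)))[-1L],
       pos = rev(cumsum(rev(pos_b)))[-1L],
       n = length(z), P = sum(y))
}

xlogx <- function(v) ifelse(v > 0, v * log(v), 0)

# Saturated-in-groups Bernoulli log-likelihood from group (cases, totals).
sat_loglik <- function(pos, tot) {
  xlogx(pos) + xlogx(tot - pos) - xlogx(tot)
}

# Grouped AUC from per-group (cases a_g, controls b_g); scores ordered by the
# observed group event fraction, ties resolved by exact cross-multiplication.
# `pos`, `tot` are lists of equally-shaped arrays, one per group.
grouped_auc <- function(pos, tot) {
  G <- length(pos)
  A <- Reduce(`+`, pos)
  tots <- Reduce(`+`, tot)
  B <- tots - A
  num <- 0
  for (g in seq_len(G)) {
    for (h in seq_len(G)) {
      # compare s_g = pos_g/tot_g with s_h via pos_g*tot_h vs pos_h*tot_g
      lhs <- pos[[g]] * tot[[h]]
      rhs <- pos[[h]] * tot[[g]]
      wgt <- ifelse(lhs > rhs, 1, ifelse(lhs == rhs, 0.5, 0))
      num <- num + pos[[g]] * (tot[[h]] - pos[[h]]) * wgt
    }
  }
  num / (A * B)
}

# --- scan engines ---------------------------------------------------------

scan_logrank <- function(tabs, K, minsz, minev) {
  a <- tabs$a; u <- tabs$u; M <- tabs$M
  size <- tabs$size; evts <- tabs$events
  n <- tabs$n; etot <- tabs$n_events
  m <- length(a)
  dM <- diag(M)
  if (K == 1L) {
    V <- u - dM
    value <- ifelse(V > 1e-12, a^2 / V, NA_real_)
    n1 <- size; n0 <- n - size
    valid <- is.finite(value) & n0 >= minsz & n1 >= minsz &
      evts >= minev & (etot - evts) >= minev
    data.frame(i = seq_len(m), j = NA_integer_, value = value,
               n0 = n0, n1 = n1, n2 = NA_real_, valid = valid)
  } else {
    ii <- matrix(seq_len(m), m, m)
    jj <- t(ii)
    mask <- ii < jj
    OE1 <- outer(a, a, "-")
    OE2 <- matrix(a, m, m, byrow = TRUE)
    V11 <- outer(u, u, "-") -
      (matrix(dM, m, m) - 2 * M + matrix(dM, m, m, byrow = TRUE))
    V12 <- matrix(dM, m, m, byrow = TRUE) - M
    V22 <- matrix(u - dM, m, m, byrow = TRUE)
    det <- V11 * V22 - V12^2
    value <- (OE1^2 * V22 - 2 * OE1 * OE2 * V12 + OE2^2 * V11) / det
    n2 <- matrix(size, m, m, byrow = TRUE)
    n1 <- matrix(size, m, m) - n2
    n0 <- n - matrix(size, m, m)
    e2 <- matrix(evts, m, m, byrow = TRUE)
    e1 <- matrix(evts, m, m) - e2
    e0 <- etot - matrix(evts, m, m)
    valid <- mask & is.finite(value) & det > 1e-10 & value >= 0 &
      n0 >= minsz & n1 >= minsz & n2 >= minsz &
      e0 >= minev & e1 >= minev & e2 >= minev
    keep <- mask
    data.frame(i = ii[keep], j = jj[keep], value = value[keep],
               n0 = n0[keep], n1 = n1[keep], n2 = n2[keep],
               valid = valid[keep])
  }
}

scan_binary <- function(tabs, K, minsz, criterion) {
  tot <- tabs$tot; pos <- tabs$pos
  n <- tabs$n; P <- tabs$P
  m <- length(tot)
  if (K == 1L) {
    g_tot <- list(n - tot, tot)
    g_pos <- list(P - pos, pos)
    idx <- data.frame(i = seq_len(m), j = NA_integer_)
  } else {
    t1 <- matrix(tot, m, m); t2 <- matrix(tot, m, m, byrow = TRUE)
    p1 <- matrix(pos, m, m); p2 <- matrix(pos, m, m, byrow = TRUE)
    mask <- matrix(seq_len(m), m, m) < matrix(seq_len(m), m, m, byrow = TRUE)
    g_tot <- list(n - t1, t1 - t2, t2)
    g_pos <- list(P - p1, p1 - p2, p2)
    ii <- matrix(seq_len(m), m, m)
    idx <- data.frame(i = ii[mask], j = t(ii)[mask])
    g_tot <- lapply(g_tot, function(x) x[mask])
    g_pos <- lapply(g_pos, function(x) x[mask])
  }
  sizes_ok <- Reduce(`&`, lapply(g_tot, function(x) x >= minsz))
  if (criterion == "logistic_lrt") {
    ll_sat <- Reduce(`+`, Map(sat_loglik, g_pos, g_tot))
    ll_null <- sat_loglik(P, n)
    value <- 2 * (ll_sat - ll_null)
    # quasi-separation: a group with all-0 or all-1 outcomes
    sep <- Reduce(`|`, Map(function(p, t) p == 0 | p == t, g_pos, g_tot))
    valid <- sizes_ok & !sep & is.finite(value)
  } else if (criterion == "chi2") {
    value <- 0
    for (g in seq_along(g_tot)) {
      E1 <- g_tot[[g]] * P / n
      E0 <- g_tot[[g]] * (n - P) / n
      value <- value + (g_pos[[g]] - E1)^2 / E1 +
        ((g_tot[[g]] - g_pos[[g]]) - E0)^2 / E0
    }
    valid <- sizes_ok & is.finite(value)
  } else if (criterion == "max_auc") {
    value <- grouped_auc(g_pos, g_tot)
    valid <- sizes_ok & is.finite(value)
  } else {
    stop("unknown binary criterion: ", criterion, call. = FALSE)
  }
  ns <- as.data.frame(stats::setNames(g_tot, paste0("n", seq_along(g_tot) - 1L)))
  if (K == 1L) ns$n2 <- NA_real_
  cbind(idx, data.frame(value = value), ns, data.frame(valid = valid))
}

# Cox LRT per tuple: loops over feasible tuples with a direct coxph.fit call
# (no formula interface) on the cumulative dummies.
cox_lrt_value <- function(X, surv_y) {
  ctl <- survival::coxph.control()
  fit <- tryCatch(
    survival::coxph.fit(X, surv_y, strata = NULL, offset = NULL,
                        init = rep(0, ncol(X)), control = ctl,
                        weights = NULL, method = "efron",
                        rownames = NULL),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$coefficients)) ||
      any(abs(fit$coefficients) > 15)) {
    return(NA_real_)
  }
  2 * (fit$loglik[2L] - fit$loglik[1L])
}

scan_cox <- function(z, time, event, cand, K, minsz, minev) {
  tabs <- threshold_surv_tables(z, time, event, cand)
  size <- tabs$size; evts <- tabs$events
  n <- tabs$n; etot <- tabs$n_events
  m <- length(cand)
  if (K == 1L) {
    base <- data.frame(i = seq_len(m), j = NA_integer_,
                       n0 = n - size, n1 = size, n2 = NA_real_)
    feas <- base$n0 >= minsz & base$n1 >= minsz &
      evts >= minev & (etot - evts) >= minev
  } else {
    ii <- matrix(seq_len(m), m, m)
    jj <- t(ii)
    mask <- ii < jj
    n2 <- matrix(size, m, m, byrow = TRUE)
    n1 <- matrix(size, m, m) - n2
    e2 <- matrix(evts, m, m, byrow = TRUE)
    e1 <- matrix(evts, m, m) - e2
    base <- data.frame(i = ii[mask], j = jj[mask],
                       n0 = (n - matrix(size, m, m))[mask],
                       n1 = n1[mask], n2 = n2[mask])
    feas <- base$n0 >= minsz & base$n1 >= minsz & base$n2 >= minsz &
      (etot - matrix(evts, m, m)[mask]) >= minev &
      e1[mask] >= minev & e2[mask] >= minev
  }
  surv_y <- survival::Surv(time, event)
  vals <- rep(NA_real_, nrow(base))
  for (r in which(feas)) {
    c1 <- cand[base$i[r]]
    X <- cbind(ge1 = as.numeric(z >= c1))
    if (K == 2L) X <- cbind(X, ge2 = as.numeric(z >= cand[base$j[r]]))
    vals[r] <- cox_lrt_value(X, surv_y)
  }
  base$value <- vals
  base$valid <- feas & is.finite(vals) & vals >= 0
  base
}

# --- public search --------------------------------------------------------

#' Locate optimal cutpoints by exhaustive criterion maximization
#'
#' Evaluates every strictly increasing K-tuple of candidate cutpoints whose
#' induced K + 1 risk groups satisfy the grid's minimum group-size (and, for
#' survival outcomes, minimum events-per-group) constraints, and returns the
#' tuple maximizing the chosen criterion: the log-rank or Cox
#' likelihood-ratio statistic (survival outcomes; the most significant
#' split), or the logistic likelihood-ratio statistic, the AUC of the fitted
#' group probabilities, or the Pearson chi-square statistic (binary
#' outcomes). Ties are broken deterministically toward the lexicographically
#' smallest cutpoints.
#'
#' Candidates that produce a degenerate fit (e.g. a group with all-0 or
#' all-1 binary outcomes, which quasi-separates the logistic model) are
#' rejected and counted in `n_invalid`.
#'
#' @param cohort a `cohort` data frame (see [as_cohort()]).
#' @param K number of cutpoints to place (1 or 2).
#' @param criterion `"logrank"` or `"cox_lrt"` (survival mode);
#'   `"logistic_lrt"`, `"max_auc"`, or `"chi2"` (binary mode). Defaults to
#'   `"logrank"` / `"logistic_lrt"` by mode.
#' @param grid a [candidate_cutpoints()] grid; computed from the cohort by
#'   default.
#' @return An object of class `cutpoint_search`: `best` (a [cutpoint_set()]),
#'   `best_value`, `criterion`, `K`, `df`, `p` (test criteria only),
#'   `surface` (data frame of every enumerated tuple with its criterion
#'   value, group sizes, and validity flag), `n_evaluated`, `n_invalid`.
#' @seealso [find_cut_number()] for choosing K, [chi2_baseline_search()].
#' @export
search_cutpoints <- function(cohort, K, criterion = NULL, grid = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  cv <- cohort_vectors(cohort)
  surv_crit <- c("logrank", "cox_lrt")
  bin_crit <- c("logistic_lrt", "max_auc", "chi2")
  if (is.null(criterion)) {
    criterion <- if (cv$mode == "survival") "logrank" else "logistic_lrt"
  }
  criterion <- match.arg(criterion, c(surv_crit, bin_crit))
  if (cv$mode == "survival" && !criterion %in% surv_crit) {
    stop("criterion `", criterion, "` requires a binary outcome", call. = FALSE)
  }
  if (cv$mode == "binary" && !criterion %in% bin_crit) {
    stop("criterion `", criterion, "` requires a survival outcome", call. = FALSE)
  }
  if (!K %in% c(1L, 2L)) stop("K must be 1 or 2", call. = FALSE)
  if (cv$mode == "survival" && sum(cv$event) < 1) {
    stop("degenerate data: no events observed", call. = FALSE)
  }
  if (cv$mode == "binary" && length(unique(cv$y)) < 2L) {
    stop("degenerate data: outcome takes a single value", call. = FALSE)
  }
  if (is.null(grid)) grid <- candidate_cutpoints(cv$z)
  cand <- grid$values
  if (length(cand) < K) stop("fewer candidates than cutpoints requested", call. = FALSE)
  minsz <- max(1L, ceiling(grid$min_group_frac * length(cv$z)))
  if (cv$mode == "survival") {
    minev <- grid$min_events_per_group
    if (criterion == "logrank") {
      tabs <- threshold_surv_tables(cv$z, cv$time, cv$event, cand)
      surf <- scan_logrank(tabs, K, minsz, minev)
    } else {
      surf <- scan_cox(cv$z, cv$time, cv$event, cand, K, minsz, minev)
    }
  } else {
    tabs <- threshold_bin_tables(cv$z, cv$y, cand)
    surf <- scan_binary(tabs, K, minsz, criterion)
  }
  surf$cut1 <- cand[surf$i]
  surf$cut2 <- if (K == 2L) cand[surf$j] else NA_real_
  surf <- surf[order(surf$cut1, surf$cut2), , drop = FALSE]
  df <- K
  if (criterion != "max_auc") {
    surf$p <- ifelse(surf$valid,
                     stats::pchisq(surf$value, df, lower.tail = FALSE),
                     NA_real_)
  }
  keep_cols <- c(paste0("cut", seq_len(K)), "value",
                 if (criterion != "max_auc") "p",
                 paste0("n", 0:K), "valid")
  surface <- surf[, keep_cols, drop = FALSE]
  rownames(surface) <- NULL
  vals <- ifelse(surf$valid, surf$value, -Inf)
  if (!any(surf$valid)) {
    stop("no feasible split: every candidate tuple violates the group ",
         "constraints or fails to fit", call. = FALSE)
  }
  best_row <- which.max(vals)  # surface sorted lexicographically; first max wins
  best <- c(surf$cut1[best_row], if (K == 2L) surf$cut2[best_row])
  structure(
    list(criterion = criterion, K = K,
         best = cutpoint_set(best), best_value = surf$value[best_row],
         df = if (criterion == "max_auc") NA_integer_ else df,
         p = if (criterion == "max_auc") NA_real_ else
           stats::pchisq(surf$value[best_row], df, lower.tail = FALSE),
         surface = surface,
         n_evaluated = sum(surf$valid), n_invalid = sum(!surf$valid),
         n = length(cv$z)),
    class = "cutpoint_search")
}

#' Baseline cutpoint search by Pearson chi-square
#'
#' The traditional contingency-table baseline: the same exhaustive scheme as
#' [search_cutpoints()], with the Pearson chi-square statistic of the
#' (K + 1) x 2 table of risk group by outcome as the criterion. Requires a
#' binary-outcome cohort.
#'
#' @inheritParams search_cutpoints
#' @return A `cutpoint_search` object with `criterion = "chi2"`.
#' @export
chi2_baseline_search <- function(cohort, K, grid = NULL) {
  cv <- cohort_vectors(cohort)
  if (cv$mode != "binary") {
    stop("chi-square baseline requires a binary outcome", call. = FALSE)
  }
  search_cutpoints(cohort, K, criterion = "chi2", grid = grid)
}

#' @export
print.cutpoint_search <- function(x, ...) {
  cat("Cutpoint search [", x$criterion, "], K =", x$K, "\n")
  cat("  best cuts:", paste(format(unclass(x$best)), collapse = ", "),
      " value =", format(x$best_value))
  if (!is.na(x$df)) cat(sprintf("  (df = %d, p = %.4g)", x$df, x$p))
  cat("\n  tuples evaluated:", x$n_evaluated, "; rejected:", x$n_invalid, "\n")
  invisible(x)
}

#' Export a search surface
#'
#' Writes the criterion surface of a [search_cutpoints()] result as a
#' tab-separated table (one row per enumerated tuple) or as JSON.
#'
#' @param result a `cutpoint_search` object.
#' @param path output file path.
#' @param format `"tsv"` (default) or `"json"`.
#' @return The path, invisibly.
#' @export
export_surface <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "cutpoint_search"))
  if (format == "tsv") {
    utils::write.table(result$surface, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    jsonlite::write_json(
      list(criterion = result$criterion, K = result$K,
           best = as.numeric(result$best), best_value = result$best_value,
           surface = result$surface),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
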