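# K-sample log-rank machinery built on per-event-time risk tables.
# The same tables drive both the user-facing test and the exhaustive
# cutpoint scans, where thousands of candidate splits share one cohort.

# Per-group at-risk and event-count matrices over the distinct event times.
# Returns G x T matrices `n_risk`, `n_event` plus totals.
risk_tables <- function(group, time, event) {
  dtimes <- sort(unique(time[event == 1]))
  tt <- length(dtimes)
  levs <- sort(unique(group))
  gi <- match(group, levs)
  # subject i is at risk at dtimes[j] iff time[i] >= dtimes[j]
  last_risk <- findInterval(time, dtimes)  # at risk for j in 1..last_risk
  gmax <- length(levs)
  n_risk <- matrix(0, gmax, tt)
  n_event <- matrix(0, gmax, tt)
  cnt <- matrix(0, gmax, tt + 1L)
  sel <- last_risk > 0L
  if (any(sel)) {
    tb <- table(factor(gi[sel], levels = seq_len(gmax)),
                factor(last_risk[sel], levels = seq_len(tt)))
    cnt[, seq_len(tt)] <- as.matrix(tb)
    # at risk at j = # subjects with last_risk >= j
    n_risk <- t(apply(cnt[, seq_len(tt), drop = FALSE], 1L,
                      function(r) rev(cumsum(rev(r)))))
    if (tt == 1L) n_risk <- matrix(n_risk, nrow = gmax)
  }
  ev <- event == 1
  if (any(ev)) {
    j <- match(time[ev], dtimes)
    tb <- table(factor(gi[ev], levels = seq_len(gmax)),
                factor(j, levels = seq_len(tt)))
    n_event <- as.matrix(tb)
  }
  list(dtimes = dtimes, levels = levs, n_risk = n_risk, n_event = n_event,
       N = colSums(n_risk), d = colSums(n_event))
}

# Observed minus expected per group and the hypergeometric covariance matrix.
logrank_oev <- function(tab) {
  N <- tab$N
  d <- tab$d
  w <- ifelse(N > 1, d * (N - d) / (N - 1), 0)
  p <- sweep(tab$n_risk, 2L, N, "/")       # n_g / N per time
  O <- rowSums(tab$n_event)
  E <- as.vector(tab$n_risk %*% (d / N))
  u <- as.vector(p %*% w)                  # sum w * n_g / N
  pw <- sweep(p, 2L, sqrt(w), "*")
  V <- diag(u, nrow = length(u)) - tcrossprod(pw)
  list(O = O, E = E, V = V)
}

#' K-sample log-rank test across ordinal risk groups
#'
#' Compares the survival experience of two or more groups via the classical
#' observed-minus-expected event counts accumulated over the risk sets at
#' each distinct event time, with the hypergeometric covariance. The default
#' heterogeneity statistic has `#groups - 1` degrees of freedom; the trend
#' variant collapses the comparison onto the ordinal group scores (0, 1, ...)
#' and has 1 degree of freedom.
#'
#' @param group vector of group labels (ordinal; all groups must be
#'   non-empty).
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicators.
#' @param type `"heterogeneity"` (default) or `"trend"`.
#' @return A `cut_test` result: `statistic`, `df`, `p`, `method`.
#' @examples
#' lr <- logrank_test(c(0, 0, 1, 1), time = c(1, 2, 3, 4), event = rep(1, 4))
#' lr$statistic  # 49/17
#' @export
logrank_test <- function(group, time, event, type = c("heterogeneity", "trend")) {
  type <- match.arg(type)
  stopifnot(length(group) == length(time), length(time) == length(event))
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (sum(event) < 1) stop("no events observed", call. = FALSE)
  if (is.factor(group) && any(table(group) == 0L)) {
    stop("empty group level in `group`", call. = FALSE)
  }
  levs <- sort(unique(group))
  if (length(levs) < 2L) stop("log-rank test needs at least 2 groups", call. = FALSE)
  tab <- risk_tables(group, time, event)
  oev <- logrank_oev(tab)
  if (type == "heterogeneity") {
    keep <- seq_along(levs)[-1L]
    U <- (oev$O - oev$E)[keep]
    V <- oev$V[keep, keep, drop = FALSE]
    stat <- tryCatch(as.numeric(crossprod(U, solve(V, U))),
                     error = function(e) NA_real_)
    df <- length(keep)
  } else {
    s <- seq_along(levs) - 1
    U <- sum(s * (oev$O - oev$E))
    Vs <- as.numeric(crossprod(s, oev$V %*% s))
    stat <- U^2 / Vs
    df <- 1L
  }
  cut_test(stat, df, method = if (type == "trend") "logrank_trend" else "logrank")
}

# Lightweight container for chi-square-referenced test results.
cut_test <- function(statistic, df, method) {
  structure(
    list(statistic = as.numeric(statistic), df = as.integer(df),
         p = stats::pchisq(as.numeric(statistic), df, lower.tail = FALSE),
         method = method),
    class = "cut_test"
  )
}

#' @export
print.cut_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, df = %d, p = %.4g\n",
              x$method, x$statistic, x$df, x$p))
  invisible(x)
}
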