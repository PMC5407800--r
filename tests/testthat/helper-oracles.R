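# Independent reference implementations used to cross-check the package's
# fast engines. Deliberately naive: plain double loops over candidate
# tuples, calling the standard R engines (survdiff, coxph, glm, chisq.test)
# or brute-force enumeration, sharing no code with the search machinery.

# Brute-force pairwise Mann-Whitney AUC.
brute_auc <- function(score, y) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Cox partial log-likelihood (Breslow form; equals Efron with untied event
# times) for a single binary covariate, evaluated on a beta grid.
cox_pll_1d <- function(beta, x, time, event) {
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  n <- length(time)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Naive exhaustive cutpoint search: loops over every candidate tuple,
# re-derives groups, re-checks constraints, and recomputes the criterion
# from scratch with the standard engines.
naive_search <- function(cohort, K, criterion, grid) {
  spec <- attr(cohort, "spec")
  z <- cohort[[spec$z]]
  cand <- grid$values
  n <- length(z)
  minsz <- max(1, ceiling(grid$min_group_frac * n))
  minev <- grid$min_events_per_group
  tuples <- if (K == 1) {
    lapply(cand, function(c) c)
  } else {
    cc <- utils::combn(cand, 2)
    lapply(seq_len(ncol(cc)), function(i) cc[, i])
  }
  best <- NULL
  bv <- -Inf
  for (cu in tuples) {
    g <- findInterval(z, cu)
    sz <- table(factor(g, levels = 0:K))
    if (any(sz < minsz)) next
    if (spec$mode == "survival") {
      t <- cohort[[spec$time]]; e <- cohort[[spec$event]]
      ev <- table(factor(g[e == 1], levels = 0:K))
      if (any(ev < minev)) next
      v <- if (criterion == "logrank") {
        survival::survdiff(survival::Surv(t, e) ~ g)$chisq
      } else {
        fit <- survival::coxph(survival::Surv(t, e) ~ factor(g),
                               ties = "efron")
        2 * (fit$loglik[2] - fit$loglik[1])
      }
    } else {
      y <- cohort[[spec$y]]
      fr <- tapply(y, factor(g, levels = 0:K), mean)
      if (criterion == "logistic_lrt") {
        if (any(fr %in% c(0, 1))) next
        full <- stats::glm(y ~ factor(g), family = stats::binomial())
        null <- stats::glm(y ~ 1, family = stats::binomial())
        v <- 2 * (as.numeric(stats::logLik(full)) -
                    as.numeric(stats::logLik(null)))
      } else if (criterion == "chi2") {
        tab <- table(factor(g, levels = 0:K), factor(y, levels = 0:1))
        v <- suppressWarnings(
          unname(stats::chisq.test(tab, correct = FALSE)$statistic))
      } else {
        v <- brute_auc(fr[as.character(g)], y)
      }
    }
    if (v > bv + 1e-9) {
      bv <- v
      best <- cu
    }
  }
  list(best = best, value = bv)
}
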