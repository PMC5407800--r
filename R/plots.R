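# Graphical aids: the smoothed hazard-ratio curve, per-group Kaplan-Meier
# curves, the AIC profile, and the search surface. All plot functions are
# pure renderers returning ggplot objects; pass `file` to also save a figure.

#' Smoothed hazard-ratio curve over a continuous risk factor
#'
#' Fits a Cox model with a natural cubic spline basis in the risk factor and
#' evaluates the fitted log hazard ratio relative to a reference value on a
#' grid spanning the observed range, with pointwise 95% bands from the
#' coefficient covariance. By default the reference is the grid point with
#' the lowest fitted hazard, so the curve shows how much riskier any value
#' is than the optimum — the visual aid for judging whether risk is
#' monotone (one cutpoint) or U-shaped (two).
#'
#' @param cohort a survival-mode `cohort`.
#' @param df_spline spline degrees of freedom (default 4).
#' @param z_ref reference value; default the curve minimizer.
#' @param n_grid number of grid points (default 100).
#' @param trim the grid spans the `[trim, 1 - trim]` quantile range of the
#'   observed risk factor (default 0.025): in the sparse extremes of the
#'   sample the spline is an unstable extrapolation, and including them
#'   lets a meaningless tail dip capture the default reference.
#' @return An object of class `hr_curve`: a data frame (`z`, `log_hr`, `hr`,
#'   `ci_low`, `ci_high` on the log scale) with attributes `z_ref` and
#'   `z_values` (the observed risk-factor values, for the histogram layer).
#' @export
smooth_hr_curve <- function(cohort, df_spline = 4, z_ref = NULL,
                            n_grid = 100, trim = 0.025) {
  stopifnot(inherits(cohort, "cohort"))
  cv <- cohort_vectors(cohort)
  if (cv$mode != "survival") {
    stop("the hazard-ratio curve requires a survival outcome", call. = FALSE)
  }
  if (length(unique(cv$z)) <= df_spline) {
    stop("too few distinct risk-factor values for a ", df_spline,
         "-df spline basis", call. = FALSE)
  }
  if (sum(cv$event) < 20) {
    warning("fewer than 20 events; the smoothed curve will be unstable")
  }
  basis <- splines::ns(cv$z, df = df_spline)
  fit <- survival::coxph(survival::Surv(cv$time, cv$event) ~ basis,
                         ties = "efron")
  qr <- stats::quantile(cv$z, c(trim, 1 - trim), names = FALSE)
  zg <- seq(qr[1L], qr[2L], length.out = n_grid)
  Bg <- stats::predict(basis, zg)
  eta <- as.vector(Bg %*% stats::coef(fit))
  if (is.null(z_ref)) {
    ref_idx <- which.min(eta)
    z_ref <- zg[ref_idx]
    Bref <- Bg[ref_idx, , drop = FALSE]
  } else {
    Bref <- stats::predict(basis, z_ref)
  }
  eta_ref <- as.vector(Bref %*% stats::coef(fit))
  D <- sweep(Bg, 2L, as.vector(Bref))
  se <- sqrt(pmax(0, rowSums((D %*% fit$var) * D)))
  log_hr <- eta - eta_ref
  out <- data.frame(z = zg, log_hr = log_hr, hr = exp(log_hr),
                    ci_low = log_hr - 1.96 * se,
                    ci_high = log_hr + 1.96 * se)
  structure(out, z_ref = z_ref, z_values = cv$z, df_spline = df_spline,
            class = c("hr_curve", "data.frame"))
}

#' @rdname smooth_hr_curve
#' @param x an `hr_curve` object.
#' @param file optional path; if given the figure is also written there.
#' @param ... ignored.
#' @export
plot.hr_curve <- function(x, file = NULL, ...) {
  dat <- as.data.frame(x)
  zv <- attr(x, "z_values")
  # scale the histogram into the lower fifth of the plotted range
  ylim <- range(c(dat$ci_low, dat$ci_high), finite = TRUE)
  h <- graphics::hist(zv, breaks = 30, plot = FALSE)
  hmax <- max(h$counts)
  hdat <- data.frame(mid = h$mids,
                     top = ylim[1] + 0.2 * diff(ylim) * h$counts / hmax,
                     bottom = ylim[1])
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = z)) +
    ggplot2::geom_rect(data = hdat,
                       ggplot2::aes(xmin = mid - diff(h$mids[1:2]) / 2.2,
                                    xmax = mid + diff(h$mids[1:2]) / 2.2,
                                    ymin = bottom, ymax = top),
                       inherit.aes = FALSE, fill = "grey80") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = log_hr), linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = attr(x, "z_ref"), linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "risk factor", y = "log hazard ratio vs reference",
                  title = sprintf("Smoothed hazard ratio (reference %.3g)",
                                  attr(x, "z_ref")))
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 7, height = 5, dpi = 150)
  p
}

#' Kaplan-Meier curves per risk group
#'
#' Step survival curves for each risk group, annotated with the log-rank
#' p-value when supplied.
#'
#' @param curves a `km_curves` object from [km_estimate()].
#' @param logrank optional `cut_test` from [logrank_test()] for the p-value
#'   annotation.
#' @param file optional output path.
#' @return A ggplot object.
#' @export
plot_km_groups <- function(curves, logrank = NULL, file = NULL) {
  stopifnot(inherits(curves, "km_curves"))
  if (nrow(curves) == 0L) stop("empty curve set", call. = FALSE)
  dat <- as.data.frame(curves)
  # prepend S(0) = 1 for each group
  starts <- do.call(rbind, lapply(split(dat, dat$group), function(d) {
    data.frame(group = d$group[1L], time = 0, n_risk = max(d$n_risk),
               n_event = 0, surv = 1)
  }))
  dat <- rbind(starts, dat)
  p <- ggplot2::ggplot(dat, ggplot2::aes(time, surv, colour = factor(group))) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (years)", y = "survival probability",
                  colour = "risk group")
  if (!is.null(logrank)) {
    p <- p + ggplot2::annotate(
      "text", x = max(dat$time) * 0.7, y = 0.95,
      label = sprintf("log-rank p = %.3g", logrank$p))
  }
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 7, height = 5, dpi = 150)
  p
}

#' Plot an AIC profile
#'
#' AIC against the number of cutpoints, with the minimizing K marked.
#'
#' @param profile an `aic_profile` from [find_cut_number()].
#' @param file optional output path.
#' @return A ggplot object.
#' @export
plot_aic_profile <- function(profile, file = NULL) {
  stopifnot(inherits(profile, "aic_profile"))
  dat <- as.data.frame(profile)[, c("K", "aic")]
  best <- attr(profile, "best_K")
  p <- ggplot2::ggplot(dat, ggplot2::aes(K, aic)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = dat[dat$K == best, , drop = FALSE],
                        colour = "firebrick", size = 3) +
    ggplot2::scale_x_continuous(breaks = dat$K) +
    ggplot2::labs(x = "number of cutpoints K", y = "AIC")
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 6, height = 4, dpi = 150)
  p
}

#' Plot a cutpoint-search surface
#'
#' For a one-cut search, the criterion value against the candidate cutpoint
#' with the maximum marked; for a two-cut search, a lower-triangular heat
#' map over (cut 1, cut 2) pairs.
#'
#' @param result a `cutpoint_search` from [search_cutpoints()].
#' @param file optional output path.
#' @return A ggplot object.
#' @export
plot_search_surface <- function(result, file = NULL) {
  stopifnot(inherits(result, "cutpoint_search"))
  surf <- result$surface[result$surface$valid, , drop = FALSE]
  if (nrow(surf) == 0L) stop("empty search surface", call. = FALSE)
  best <- as.numeric(result$best)
  if (result$K == 1L) {
    p <- ggplot2::ggplot(surf, ggplot2::aes(cut1, value)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = best[1L], linetype = 2,
                          colour = "firebrick") +
      ggplot2::labs(x = "candidate cutpoint",
                    y = paste(result$criterion, "criterion"))
  } else {
    p <- ggplot2::ggplot(surf, ggplot2::aes(cut1, cut2, fill = value)) +
      ggplot2::geom_tile() +
      ggplot2::annotate("point", x = best[1L], y = best[2L],
                        colour = "firebrick", size = 2) +
      ggplot2::scale_fill_viridis_c(name = result$criterion) +
      ggplot2::labs(x = "cutpoint 1", y = "cutpoint 2")
  }
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 6, height = 5, dpi = 150)
  p
}
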