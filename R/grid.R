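#' Admissible candidate cutpoints for a risk factor
#'
#' The candidate grid defaults to the sorted distinct observed values of the
#' risk factor (a reported cutpoint is then always an observable value);
#' optionally the midpoints between adjacent distinct values are used
#' instead. A candidate is excluded when, used alone as a single cut, it
#' would leave either of the two induced groups with fewer than
#' `ceiling(min_group_frac * n)` subjects (at least 1). Minimum-group and
#' minimum-event constraints are re-applied jointly to every multi-cut tuple
#' during the search.
#'
#' @param z numeric vector of observed risk-factor values (>= 2 distinct).
#' @param min_group_frac minimum fraction of subjects per induced group
#'   (default 0.10). Unconstrained minimal-p searches are unstable at the
#'   edges of the observed range; the floor makes the search well-posed.
#' @param min_events_per_group minimum number of events per group, enforced
#'   tuple-wise in survival-mode searches (default 5).
#' @param midpoints if `TRUE`, use midpoints between adjacent distinct
#'   values instead of the observed values themselves.
#' @return An object of class `candidate_grid` with fields `values`,
#'   `min_group_frac`, `min_events_per_group`.
#' @examples
#' candidate_cutpoints(1:10, min_group_frac = 0.2)$values  # 3..9
#' @export
candidate_cutpoints <- function(z, min_group_frac = 0.10,
                                min_events_per_group = 5,
                                midpoints = FALSE) {
  z <- as.numeric(z)
  z <- z[is.finite(z)]
  uz <- sort(unique(z))
  if (length(uz) < 2L) {
    stop("no candidate cutpoints: risk factor has fewer than 2 distinct values",
         call. = FALSE)
  }
  vals <- if (midpoints) (uz[-1L] + uz[-length(uz)]) / 2 else uz
  n <- length(z)
  minsz <- max(1L, ceiling(min_group_frac * n))
  upper <- vapply(vals, function(c) sum(z >= c), numeric(1))
  keep <- upper >= minsz & (n - upper) >= minsz
  vals <- vals[keep]
  if (length(vals) == 0L) {
    stop("no candidate cutpoints satisfy the minimum group-size constraint",
         call. = FALSE)
  }
  structure(list(values = vals, min_group_frac = min_group_frac,
                 min_events_per_group = min_events_per_group),
            class = "candidate_grid")
}

#' @export
print.candidate_grid <- function(x, ...) {
  cat("Candidate grid:", length(x$values), "cutpoint value(s) in [",
      format(min(x$values)), ",", format(max(x$values)), "];",
      "min group fraction", x$min_group_frac, ";",
      "min events/group", x$min_events_per_group, "\n")
  invisible(x)
}
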