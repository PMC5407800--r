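#' Construct a set of cutpoints
#'
#' A cutpoint set is a strictly increasing vector of K thresholds on the
#' risk-factor scale, defining K + 1 ordinal risk groups. The empty set is
#' legal and corresponds to a single group.
#'
#' @param cuts numeric vector of thresholds (may be empty).
#' @return A numeric vector of class `cutpoint_set`.
#' @export
cutpoint_set <- function(cuts = numeric()) {
  cuts <- as.numeric(cuts)
  if (anyNA(cuts) || any(!is.finite(cuts))) {
    stop("cutpoints must be finite", call. = FALSE)
  }
  if (length(cuts) > 1L && any(diff(cuts) <= 0)) {
    stop("cutpoints must be strictly increasing", call. = FALSE)
  }
  structure(cuts, class = "cutpoint_set")
}

#' @export
print.cutpoint_set <- function(x, ...) {
  k <- length(x)
  if (k == 0L) cat("Cutpoint set: (none; single risk group)\n")
  else cat("Cutpoint set: K =", k, "->", paste(format(unclass(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Categorize a continuous risk factor at given cutpoints
#'
#' A subject with value `v` is assigned ordinal group `#{c in cuts : v >= c}`,
#' so a value exactly equal to a cutpoint joins the *upper* group ("at or
#' larger than the threshold" is high risk). The groups are also represented
#' by dummy variables: with the default cumulative coding the k-th dummy is 1
#' iff the group index is at least k, so each regression coefficient is the
#' log hazard/odds increment between adjacent groups; with one-hot coding each
#' dummy indicates one non-reference group (group 0 is the reference). The two
#' codings are linear reparameterizations and give identical model fits.
#'
#' @param z numeric vector of risk-factor values.
#' @param cuts a [cutpoint_set()] or plain numeric vector of strictly
#'   increasing thresholds; may be empty.
#' @param coding `"cumulative"` (default) or `"onehot"`.
#' @return An object of class `group_assignment`: a list with `group`
#'   (integer vector in 0..K), `dummies` (n x K indicator matrix), `K`,
#'   `cuts`, and `coding`.
#' @examples
#' encode_groups(c(4, 5, 6), cuts = 5)$group           # 0 1 1
#' encode_groups(c(0.10, 0.50, 0.99), c(0.32, 0.97))$group  # 0 1 2
#' @export
encode_groups <- function(z, cuts, coding = c("cumulative", "onehot")) {
  coding <- match.arg(coding)
  cuts <- unclass(cutpoint_set(cuts))
  z <- as.numeric(z)
  k <- length(cuts)
  group <- findInterval(z, cuts)  # counts cuts <= z: the ">= joins upper" rule
  if (k == 0L) {
    dummies <- matrix(numeric(0), nrow = length(z), ncol = 0L)
  } else if (coding == "cumulative") {
    dummies <- vapply(seq_len(k), function(j) as.numeric(group >= j),
                      numeric(length(z)))
    dummies <- matrix(dummies, nrow = length(z),
                      dimnames = list(NULL, paste0("ge_grp", seq_len(k))))
  } else {
    dummies <- vapply(seq_len(k), function(j) as.numeric(group == j),
                      numeric(length(z)))
    dummies <- matrix(dummies, nrow = length(z),
                      dimnames = list(NULL, paste0("grp", seq_len(k))))
  }
  structure(list(group = as.integer(group), dummies = dummies,
                 K = k, cuts = cuts, coding = coding),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("Group assignment: K =", x$K, "cutpoint(s)")
  if (x$K) cat(" at", paste(format(x$cuts), collapse = ", "))
  cat(" [", x$coding, " coding]\n", sep = "")
  print(table(group = x$group))
  invisible(x)
}
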