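#' Declare the outcome structure of a cohort table
#'
#' An outcome specification names the risk-factor column and the outcome
#' columns of a per-subject table, and fixes the outcome mode: `"survival"`
#' (right-censored time-to-event, requiring a follow-up time and a 0/1 event
#' indicator) or `"binary"` (a 0/1 response).
#'
#' @param mode `"survival"` or `"binary"`.
#' @param z name of the continuous risk-factor column.
#' @param time,event column names for follow-up time (years) and event
#'   indicator (1 = event observed, 0 = censored); survival mode only.
#' @param y column name of the 0/1 outcome; binary mode only.
#' @param covariates character vector of adjustment-covariate column names
#'   (continuous or categorical), used by [validate_holdout()].
#' @param id optional subject-identifier column name.
#' @return An object of class `outcome_spec`.
#' @examples
#' outcome_spec("survival", z = "bmi", time = "os_years", event = "death")
#' outcome_spec("binary", z = "tumor_size", y = "node_metastasis")
#' @export
outcome_spec <- function(mode = c("survival", "binary"), z,
                         time = NULL, event = NULL, y = NULL,
                         covariates = character(), id = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.character(z), length(z) == 1L)
  if (mode == "survival") {
    if (is.null(time) || is.null(event)) {
      stop("survival mode requires `time` and `event` column names",
           call. = FALSE)
    }
  } else {
    if (is.null(y)) stop("binary mode requires a `y` column name", call. = FALSE)
  }
  structure(
    list(mode = mode, z = z, time = time, event = event, y = y,
         covariates = as.character(covariates), id = id),
    class = "outcome_spec"
  )
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat("Outcome spec [", x$mode, "]: z =", x$z)
  if (x$mode == "survival") cat(", time =", x$time, ", event =", x$event)
  else cat(", y =", x$y)
  if (length(x$covariates)) cat(", covariates:", paste(x$covariates, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Attach an outcome specification to an in-memory data frame
#'
#' Validates the declared columns (presence, binary coding of event/y,
#' non-negative times, finite risk-factor values), drops rows with missing
#' risk-factor or outcome values (reporting the count), and returns a typed
#' cohort table.
#'
#' @param data a data frame with one row per subject.
#' @param spec an [outcome_spec()].
#' @return A data frame of class `cohort` carrying the spec as an attribute
#'   and the number of dropped rows as attribute `"n_dropped"`.
#' @export
as_cohort <- function(data, spec) {
  stopifnot(is.data.frame(data), inherits(spec, "outcome_spec"))
  needed <- c(spec$z, spec$time, spec$event, spec$y, spec$covariates, spec$id)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("column(s) not found in cohort table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data[[spec$z]] <- as.numeric(data[[spec$z]])
  outcome_cols <- if (spec$mode == "survival") c(spec$time, spec$event) else spec$y
  keep <- is.finite(data[[spec$z]])
  for (cl in outcome_cols) keep <- keep & !is.na(data[[cl]])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropped ", n_dropped,
            " row(s) with missing risk-factor or outcome values")
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) == 0L) stop("no complete rows left in cohort", call. = FALSE)
  if (spec$mode == "survival") {
    tm <- as.numeric(data[[spec$time]])
    ev <- data[[spec$event]]
    if (any(tm < 0)) stop("negative follow-up times", call. = FALSE)
    if (!all(ev %in% c(0, 1))) {
      stop("event column `", spec$event, "` must be coded 0/1", call. = FALSE)
    }
    data[[spec$time]] <- tm
    data[[spec$event]] <- as.integer(ev)
  } else {
    yy <- data[[spec$y]]
    if (!all(yy %in% c(0, 1))) {
      stop("outcome column `", spec$y, "` must be coded 0/1", call. = FALSE)
    }
    data[[spec$y]] <- as.integer(yy)
  }
  structure(data, spec = spec, n_dropped = n_dropped,
            class = c("cohort", "data.frame"))
}

#' Read a delimited cohort file
#'
#' Reads a CSV or TSV file with a header row and validates it against the
#' outcome specification via [as_cohort()]. The delimiter is inferred from
#' the file extension (`.tsv`/`.txt` are tab-separated) unless given.
#'
#' @param path path to a delimited text file with a header row.
#' @param spec an [outcome_spec()].
#' @param sep field separator; default inferred from the extension.
#' @return A `cohort` data frame.
#' @export
load_cohort <- function(path, spec, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  as_cohort(raw, spec)
}

#' @export
print.cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("Cohort:", nrow(x), "subjects,", spec$mode, "outcome (z =", spec$z)
  if (spec$mode == "survival") {
    cat("; events =", sum(x[[spec$event]]), ")\n")
  } else {
    cat("; cases =", sum(x[[spec$y]]), ")\n")
  }
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

# Extract standardized vectors from a cohort; internal convenience.
cohort_vectors <- function(cohort) {
  spec <- attr(cohort, "spec")
  out <- list(z = cohort[[spec$z]], mode = spec$mode, spec = spec)
  if (spec$mode == "survival") {
    out$time <- cohort[[spec$time]]
    out$event <- cohort[[spec$event]]
  } else {
    out$y <- cohort[[spec$y]]
  }
  out
}

#' Reproducibly split a cohort into training and testing sets
#'
#' Simple random sampling without replacement; the same seed always produces
#' the same partition. The union of the two parts is the input cohort and the
#' intersection is empty.
#'
#' @param cohort a `cohort` data frame.
#' @param n_train number of subjects in the training part; must satisfy
#'   `0 < n_train < nrow(cohort)`.
#' @param seed integer seed controlling the draw.
#' @return A list with elements `train` and `test`, both `cohort` objects.
#' @examples
#' \donttest{
#' cfg <- scenario_config("tumor_size", n = 797, seed = 1)
#' cohort <- simulate_binary_cohort(cfg)
#' parts <- split_cohort(cohort, n_train = 497, seed = 42)
#' sapply(parts, nrow)  # 497 300
#' }
#' @export
split_cohort <- function(cohort, n_train, seed) {
  stopifnot(inherits(cohort, "cohort"))
  n <- nrow(cohort)
  if (!is.numeric(n_train) || n_train <= 0 || n_train >= n) {
    stop("`n_train` must lie strictly between 0 and ", n, call. = FALSE)
  }
  idx <- with_seed(as.integer(seed), sample.int(n, size = n_train))
  spec <- attr(cohort, "spec")
  train <- as_cohort(as.data.frame(cohort)[idx, , drop = FALSE], spec)
  test <- as_cohort(as.data.frame(cohort)[-idx, , drop = FALSE], spec)
  list(train = train, test = test, seed = as.integer(seed))
}
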