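#' Assemble a collection of study summaries
#'
#' A study collection holds, for each of \eqn{k} independent studies of the
#' same emission factor, the sample size \eqn{n_i}, the sample mean
#' \eqn{\bar f_i} and (optionally) the sample standard deviation \eqn{S_i}.
#' It is the common input to all pooling estimators in this package.
#'
#' @param study character vector of study labels.
#' @param n integer vector of per-study sample sizes, or a single value
#'   recycled to all studies. May be `NULL` when only operations that do not
#'   need sample sizes will be used (they will then error).
#' @param mean numeric vector of per-study sample means, in emission-factor
#'   units (e.g. kg CH4 per ton).
#' @param sd optional numeric vector of per-study sample standard deviations,
#'   same units as `mean`. Any study reporting an `sd` must have `n >= 2`.
#'
#' @return An object of class `study_collection`: a data frame with columns
#'   `study`, `n`, `mean`, `sd` and attributes `k` (number of studies) and
#'   `N` (total number of observations, `sum(n)`).
#'
#' @examples
#' study_collection(c("A", "B"), n = c(10, 12), mean = c(20.7, 28.6),
#'                  sd = c(0.8, 0.3))
#' @export
study_collection <- function(study, n = NULL, mean, sd = NULL) {
  k <- length(mean)
  if (k < 1L) stop("a study collection needs at least one study")
  study <- as.character(study)
  if (length(study) != k) stop("'study' and 'mean' lengths differ")
  if (anyDuplicated(study)) warning("duplicate study ids: ",
    paste(unique(study[duplicated(study)]), collapse = ", "))
  if (!is.null(n)) {
    if (length(n) == 1L) n <- rep(n, k)
    if (length(n) != k) stop("'n' must have length 1 or length(mean)")
    if (any(!is.finite(n)) || any(n < 1) || any(n != round(n)))
      stop("sample sizes must be positive integers")
    n <- as.integer(n)
  } else {
    n <- rep(NA_integer_, k)
  }
  if (any(!is.finite(mean))) stop("study means must be finite")
  if (!is.null(sd)) {
    if (length(sd) != k) stop("'sd' must match the number of studies")
    if (any(!is.na(sd) & sd < 0)) stop("standard deviations must be >= 0")
    bad <- !is.na(sd) & !is.na(n) & n < 2
    if (any(bad))
      stop("study ", paste(study[bad], collapse = ", "),
           ": a single observation has no sample standard deviation")
  } else {
    sd <- rep(NA_real_, k)
  }
  out <- data.frame(study = study, n = n, mean = as.numeric(mean),
                    sd = as.numeric(sd), stringsAsFactors = FALSE)
  class(out) <- c("study_collection", "data.frame")
  out
}

#' Coerce a data frame to a study collection
#'
#' @param x a data frame with columns `study` (or `site`), `mean`, and
#'   optionally `n` and `sd`; or an existing `study_collection`.
#' @param n optional common sample size applied to every study when the data
#'   carry no `n` column (the assumed-equal-sizes situation that arises when
#'   published summaries omit sample sizes).
#' @return A `study_collection`.
#' @export
as_study_collection <- function(x, n = NULL) {
  if (inherits(x, "study_collection") && is.null(n)) return(x)
  x <- as.data.frame(x)
  nm <- names(x)
  if (!("study" %in% nm) && "site" %in% nm) names(x)[nm == "site"] <- "study"
  if (!all(c("study", "mean") %in% names(x)))
    stop("need columns 'study' and 'mean'")
  nn <- if (!is.null(n)) n else if ("n" %in% names(x)) x$n else NULL
  study_collection(x$study, n = nn, mean = x$mean,
                   sd = if ("sd" %in% names(x)) x$sd else NULL)
}

#' @export
print.study_collection <- function(x, ...) {
  cat("Study collection: k =", n_studies(x))
  if (!anyNA(x$n)) cat(", N =", total_n(x))
  cat("\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Number of studies in a collection
#' @param x a `study_collection`.
#' @return Integer count of studies \eqn{k}.
#' @export
n_studies <- function(x) nrow(x)

#' Total number of observations in a collection
#' @param x a `study_collection`.
#' @return \eqn{N = \sum n_i}; errors if any sample size is unknown.
#' @export
total_n <- function(x) {
  if (anyNA(x$n))
    stop("unknown sample size for study ",
         paste(x$study[is.na(x$n)], collapse = ", "),
         "; supply n via as_study_collection(x, n = ...)")
  sum(x$n)
}

# internal guard used by variance estimators
.require_sds <- function(x, caller) {
  if (anyNA(x$sd))
    stop(caller, " needs a standard deviation for every study; missing for ",
         paste(x$study[is.na(x$sd)], collapse = ", "))
  if (any(x$n < 2))
    stop(caller, ": studies with a single observation (",
         paste(x$study[x$n < 2], collapse = ", "),
         ") carry no within-study variance information")
  invisible(x)
}

#' Summarise raw per-observation data into a study collection
#'
#' @param raw either a data frame with columns `study` and `value`, or a
#'   named list of numeric vectors (one vector of observations per study).
#' @return A `study_collection` with the exact per-study `n`, `mean`, `sd`.
#' @export
summarise_raw <- function(raw) {
  raw <- .as_raw_list(raw)
  study_collection(names(raw),
                   n = vapply(raw, length, 1L),
                   mean = vapply(raw, mean, 1.0),
                   sd = vapply(raw, function(v)
                     if (length(v) >= 2) stats::sd(v) else NA_real_, 1.0))
}

# normalise raw input to a named list of numeric vectors
.as_raw_list <- function(raw) {
  if (is.data.frame(raw)) {
    if (!all(c("study", "value") %in% names(raw)))
      stop("raw data frame needs columns 'study' and 'value'")
    raw <- split(as.numeric(raw$value), factor(raw$study, unique(raw$study)))
  }
  if (!is.list(raw) || length(raw) < 1L)
    stop("raw data must be a non-empty list of numeric vectors")
  if (is.null(names(raw)) || any(names(raw) == ""))
    names(raw) <- paste0("study", seq_along(raw))
  raw <- lapply(raw, as.numeric)
  if (any(vapply(raw, length, 1L) < 1L)) stop("every study needs at least one observation")
  if (!all(vapply(raw, function(v) all(is.finite(v)), TRUE)))
    stop("raw observations must be finite")
  raw
}
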