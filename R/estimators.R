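#' Overall mean emission factor
#'
#' The sample-size weighted average of the study means,
#' \deqn{\hat\mu = \bar{\bar f} = \sum_i n_i \bar f_i / \sum_i n_i,}
#' the unbiased and efficient point estimator of the common mean when all
#' studies sample the same homogeneous population. With equal \eqn{n_i} it
#' reduces to the plain average of the study means.
#'
#' @param collection a [study_collection()] (or coercible data frame).
#' @return The pooled point estimate of the mean, a single number.
#' @examples
#' cs <- rice_case_study()
#' overall_mean(cs)  # 25.565 kg CH4 / ton
#' @export
overall_mean <- function(collection) {
  x <- as_study_collection(collection)
  N <- total_n(x)
  sum(x$n * x$mean) / N
}

# constructor for the classed variance-estimate container
new_variance_estimate <- function(value, df, method,
                                  estimator_variance = NULL, sums = NULL) {
  stopifnot(value >= 0, df >= 1)
  structure(list(value = value, df = df, method = method,
                 estimator_variance = estimator_variance, sums = sums),
            class = "variance_estimate")
}

#' @export
print.variance_estimate <- function(x, digits = 4, ...) {
  lab <- c(pooled = "pooled within-study variance (S2p)",
           between_means = "between-means variance (n*S2m)",
           anova = "ANOVA total-variance estimator (S2a)",
           raw_total = "total sample variance (S2)")[x$method]
  cat(lab, "\n  estimate:", format(x$value, digits = digits),
      "  df:", x$df, "\n")
  if (!is.null(x$sums))
    cat("  SST =", format(x$sums$sst, digits = digits),
        " SSW =", format(x$sums$ssw, digits = digits),
        " SSB =", format(x$sums$ssb, digits = digits), "\n")
  invisible(x)
}

#' Pooled within-study variance
#'
#' The degrees-of-freedom weighted average of the study sample variances,
#' \deqn{S^2_p = \sum_i (n_i - 1) S_i^2 / \sum_i (n_i - 1),}
#' with \eqn{df_p = \sum_i (n_i - 1)}. Under independent normal sampling with
#' a common variance, \eqn{df_p S^2_p / \sigma^2} is chi-square distributed
#' with \eqn{df_p} degrees of freedom. This estimator ignores dispersion
#' between the study means.
#'
#' @inheritParams overall_mean
#' @return A `variance_estimate` with `value`, `df` and `method = "pooled"`.
#' @examples
#' pooled_variance(rice_case_study())  # 0.82 (kg/ton)^2, df 27
#' @export
pooled_variance <- function(collection) {
  x <- as_study_collection(collection)
  total_n(x)
  .require_sds(x, "pooled_variance")
  df <- sum(x$n - 1L)
  if (df < 1) stop("pooled variance needs at least one study with n >= 2")
  new_variance_estimate(sum((x$n - 1L) * x$sd^2) / df, df, "pooled")
}

#' Between-means variance estimator
#'
#' Uses only the study means: the sample variance of the \eqn{k} means,
#' \deqn{S^2_m = \sum_i (\bar f_i - \bar{\bar f})^2 / (k - 1),}
#' estimates \eqn{\sigma^2 / n} when every study averages \eqn{n}
#' observations, so \eqn{n S^2_m} estimates \eqn{\sigma^2} with
#' \eqn{df_m = k - 1}. The common per-study size \eqn{n} must be known (or
#' assumed): the estimate grows linearly in it, so a wrong \eqn{n} scales the
#' answer proportionally.
#'
#' @inheritParams overall_mean
#' @param n_assumed the common per-study sample size used to scale
#'   \eqn{S^2_m} up to an estimate of the observation-level variance.
#'   Defaults to the collection's common `n` when all sizes are equal.
#' @return A `variance_estimate` with `method = "between_means"`, `df = k - 1`.
#' @examples
#' between_means_variance(rice_case_study())  # 180.12, df 2
#' @export
between_means_variance <- function(collection, n_assumed = NULL) {
  x <- as_study_collection(collection)
  k <- n_studies(x)
  if (k < 2) stop("between-means variance needs at least two studies")
  if (is.null(n_assumed)) {
    if (anyNA(x$n) || length(unique(x$n)) != 1L)
      stop("supply n_assumed: sample sizes are unknown or unequal")
    n_assumed <- x$n[1]
  }
  if (!is.finite(n_assumed) || n_assumed < 1)
    stop("n_assumed must be a positive integer")
  s2m <- stats::var(x$mean)  # equally-weighted grand mean, the common-n setting
  new_variance_estimate(n_assumed * s2m, k - 1L, "between_means")
}

#' ANOVA weights for combining the variance estimators
#'
#' The weights that turn the convex combination
#' \eqn{w_1 S^2_p + w_2\, n S^2_m} into the total sample variance
#' \eqn{SST/(N-1)}:
#' \deqn{w_1 = \frac{\sum_i (n_i - 1)}{N - 1}, \qquad w_2 = \frac{k - 1}{N - 1},}
#' with \eqn{N = \sum_i n_i}. They sum to one exactly, and they are the
#' degrees-of-freedom shares of the within- and between-group sums of squares
#' in a one-way ANOVA.
#'
#' @inheritParams overall_mean
#' @return Named numeric vector `c(w1, w2)`.
#' @examples
#' anova_weights(rice_case_study())  # 27/29 and 2/29
#' @export
anova_weights <- function(collection) {
  x <- as_study_collection(collection)
  N <- total_n(x)
  if (N < 2) stop("weights undefined for a single observation (N - 1 = 0)")
  k <- n_studies(x)
  c(w1 = sum(x$n - 1L) / (N - 1L), w2 = (k - 1L) / (N - 1L))
}

#' ANOVA-based variance estimator from study summaries
#'
#' Combines within-study and between-study dispersion into a single unbiased
#' estimator of the population variance:
#' \deqn{S^2_a = w_1 S^2_p + w_2\, n S^2_m = \frac{SSW + SSB}{N - 1} = \frac{SST}{N-1},}
#' the total sample variance that would be computed from the raw
#' observations, recovered from summaries alone. By the law of total variance
#' the identity holds exactly, so \eqn{(N-1) S^2_a / \sigma^2} is chi-square
#' with \eqn{N - 1} degrees of freedom — more degrees of freedom (hence a
#' smaller sampling variance) than either component alone.
#'
#' Unequal sample sizes are handled through the general between-group sum
#' \eqn{SSB = \sum_i n_i (\bar f_i - \bar{\bar f})^2} with the
#' \eqn{n_i}-weighted grand mean, which keeps the raw-data identity exact.
#'
#' @inheritParams overall_mean
#' @return A `variance_estimate` with `method = "anova"`, `df = N - 1`, and a
#'   `sums` component holding the implied `(sst, ssw, ssb)` decomposition.
#' @examples
#' anova_variance(rice_case_study())  # 13.19, df 29
#' @export
anova_variance <- function(collection) {
  x <- as_study_collection(collection)
  N <- total_n(x)
  if (N < 2) stop("variance undefined for a single observation")
  .require_sds(x, "anova_variance")
  ssw <- sum((x$n - 1L) * x$sd^2)
  gm <- sum(x$n * x$mean) / N
  ssb <- sum(x$n * (x$mean - gm)^2)
  new_variance_estimate((ssw + ssb) / (N - 1L), N - 1L, "anova",
                        sums = list(sst = ssw + ssb, ssw = ssw, ssb = ssb))
}

#' ANOVA-based variance estimator from raw observations
#'
#' With the individual observations in hand the estimator is simply the total
#' sample variance \eqn{S^2 = SST / (N - 1)}, where
#' \eqn{SST = \sum_{ij} (f_{ij} - \bar{\bar f})^2} decomposes as
#' \eqn{SST = SSW + SSB} (law of total variance). Numerically identical to
#' [anova_variance()] applied to the exact per-study summaries.
#'
#' @param raw raw observations: a data frame with columns `study`, `value`,
#'   or a named list of numeric vectors.
#' @return A `variance_estimate` with `method = "raw_total"`, `df = N - 1`,
#'   and the `(sst, ssw, ssb)` decomposition in its `sums` component.
#' @examples
#' anova_variance_raw(list(a = c(1, 2, 3), b = c(4, 5, 6)))  # 3.5
#' @export
anova_variance_raw <- function(raw) {
  raw <- .as_raw_list(raw)
  ni <- vapply(raw, length, 1L)
  N <- sum(ni)
  if (N < 2) stop("variance undefined for fewer than two observations")
  all_obs <- unlist(raw, use.names = FALSE)
  gm <- mean(all_obs)
  means <- vapply(raw, mean, 1.0)
  ssw <- sum(vapply(raw, function(v) sum((v - mean(v))^2), 1.0))
  ssb <- sum(ni * (means - gm)^2)
  sst <- sum((all_obs - gm)^2)
  new_variance_estimate(sst / (N - 1L), N - 1L, "raw_total",
                        sums = list(sst = sst, ssw = ssw, ssb = ssb))
}

#' Theoretical sampling variance of a variance estimator
#'
#' Each estimator is a scaled chi-square variable with its own degrees of
#' freedom \eqn{df}, hence has sampling variance \eqn{2\sigma^4 / df}:
#' \deqn{Var(S^2_p) = \frac{2\sigma^4}{\sum_i (n_i-1)}, \quad
#'       Var(n S^2_m) = \frac{2\sigma^4}{k-1}, \quad
#'       Var(S^2_a) = \frac{2\sigma^4}{N-1}.}
#' Since \eqn{N - 1 \ge \sum_i(n_i-1) \ge k - 1} always,
#' \eqn{Var(S^2_a) \le Var(S^2_p) \le Var(n S^2_m)}: the ANOVA estimator is
#' never less precise.
#'
#' @param method one of `"pooled"`, `"between_means"`, `"anova"`.
#' @param sigma2 the true population variance at which to evaluate.
#' @param collection a [study_collection()] supplying the design
#'   (\eqn{k} and the \eqn{n_i}).
#' @return The sampling variance, a single number (fourth-power units).
#' @examples
#' d <- study_collection(letters[1:4], n = 5, mean = rep(0, 4), sd = rep(1, 4))
#' estimator_sampling_variance("anova", 1, d)   # 2/19
#' estimator_sampling_variance("pooled", 1, d)  # 2/16
#' @export
estimator_sampling_variance <- function(method, sigma2, collection) {
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  x <- as_study_collection(collection)
  df <- switch(match.arg(method, c("pooled", "between_means", "anova")),
               pooled = sum(x$n - 1L),
               between_means = n_studies(x) - 1L,
               anova = total_n(x) - 1L)
  if (df < 1) stop("no degrees of freedom for method '", method, "'")
  2 * sigma2^2 / df
}
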