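#' Confidence interval for the mean emission factor
#'
#' Student-t interval about the pooled point estimate,
#' \deqn{\bar{\bar f} \pm t_{df,\alpha/2}\; s / \sqrt N,}
#' where \eqn{s^2} is the supplied variance estimate and \eqn{df} its degrees
#' of freedom (\eqn{N - 1} for the ANOVA estimator). A tighter variance
#' estimator — more degrees of freedom for the same value — yields a tighter
#' interval for the mean.
#'
#' @param point the point estimate of the mean (see [overall_mean()]).
#' @param variance_estimate a `variance_estimate` for the population variance.
#' @param N total number of observations behind `point`.
#' @param level confidence level in (0, 1); default 0.95.
#' @return An `ef_ci` object: list with `parameter = "mu"`, `lower`, `upper`,
#'   `level`, `df`, `point`. The interval is symmetric about `point`.
#' @examples
#' cs <- rice_case_study()
#' ci_mean(overall_mean(cs), anova_variance(cs), N = total_n(cs))
#' @export
ci_mean <- function(point, variance_estimate, N, level = 0.95) {
  .check_level(level)
  stopifnot(inherits(variance_estimate, "variance_estimate"), N >= 2)
  half <- stats::qt(1 - (1 - level) / 2, df = variance_estimate$df) *
    sqrt(variance_estimate$value / N)
  structure(list(parameter = "mu", lower = point - half, upper = point + half,
                 level = level, df = variance_estimate$df, point = point),
            class = "ef_ci")
}

#' Confidence interval for the population variance
#'
#' Chi-square interval exploiting the scaled chi-square distribution of the
#' variance estimator:
#' \deqn{\left[\frac{df\,S^2}{\chi^2_{1-\alpha/2;\,df}},\;
#'             \frac{df\,S^2}{\chi^2_{\alpha/2;\,df}}\right].}
#' The interval is non-symmetric (longer above the point estimate) and its
#' lower bound is never negative.
#'
#' @inheritParams ci_mean
#' @return An `ef_ci` with `parameter = "sigma2"`.
#' @examples
#' ci_variance(anova_variance(rice_case_study()))  # about [8.37, 23.84]
#' @export
ci_variance <- function(variance_estimate, level = 0.95) {
  .check_level(level)
  stopifnot(inherits(variance_estimate, "variance_estimate"))
  df <- variance_estimate$df
  if (df < 1) stop("variance interval needs df >= 1")
  s2 <- variance_estimate$value
  a <- 1 - level
  structure(list(parameter = "sigma2",
                 lower = df * s2 / stats::qchisq(1 - a / 2, df),
                 upper = df * s2 / stats::qchisq(a / 2, df),
                 level = level, df = df, point = s2),
            class = "ef_ci")
}

.check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1)
    stop("confidence level must lie strictly between 0 and 1")
  invisible(level)
}

#' @export
print.ef_ci <- function(x, digits = 4, ...) {
  cat(sprintf("%d%% CI for %s (df = %d): [%s, %s], point %s\n",
              round(100 * x$level),
              if (x$parameter == "mu") "mean" else "variance",
              x$df, format(x$lower, digits = digits),
              format(x$upper, digits = digits),
              format(x$point, digits = digits)))
  invisible(x)
}
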