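#' Inverse-variance weighted consensus mean
#'
#' The classical fixed-effect meta-analysis estimator: weights proportional
#' to \eqn{n_i / \sigma_i^2} minimise the variance of the weighted mean when
#' the true per-study variances are known,
#' \deqn{\hat\mu = \sum_i w_i \bar f_i / \sum_i w_i, \qquad w_i = n_i/\sigma_i^2.}
#' With equal variances it reduces exactly to [overall_mean()]. Variances at
#' (or numerically indistinguishable from) zero are rejected: a variance
#' erroneously reported as near zero would dominate the weighting and drag
#' the consensus arbitrarily far from the remaining studies.
#'
#' @inheritParams overall_mean
#' @param variances per-study true (or assumed-true) variances
#'   \eqn{\sigma_i^2}, all strictly positive.
#' @return A `consensus_mean` object: list with `mean`, normalised `weights`,
#'   `method`.
#' @export
inverse_variance_mean <- function(collection, variances) {
  x <- as_study_collection(collection)
  total_n(x)
  k <- n_studies(x)
  if (length(variances) != k) stop("'variances' must match the number of studies")
  if (any(!is.finite(variances)) || any(variances <= 0))
    stop("all variances must be strictly positive")
  guard <- 1e-12 * stats::median(variances)
  if (any(variances < guard))
    stop("study ", paste(x$study[variances < guard], collapse = ", "),
         ": variance indistinguishable from zero; near-zero reported ",
         "variances act as outliers and would dominate the weighting")
  w <- x$n / variances
  w <- w / sum(w)
  new_consensus(sum(w * x$mean), w, "inverse_variance")
}

#' Graybill-Deal consensus mean
#'
#' Plug-in version of inverse-variance weighting for the common practical
#' case where the true variances are unknown: weights \eqn{w_i = n_i/S_i^2}
#' use the reported sample variances. The estimator is simple but its exact
#' sampling distribution is intractable because the random \eqn{S_i^2}
#' appear in the weights; it is provided for comparison with the
#' sample-size-weighted [overall_mean()].
#'
#' @inheritParams overall_mean
#' @return A `consensus_mean` with `method = "graybill_deal"`.
#' @export
graybill_deal_mean <- function(collection) {
  x <- as_study_collection(collection)
  total_n(x)
  .require_sds(x, "graybill_deal_mean")
  if (any(x$sd == 0))
    stop("study ", paste(x$study[x$sd == 0], collapse = ", "),
         ": zero sample variance cannot be inverse-variance weighted")
  w <- x$n / x$sd^2
  w <- w / sum(w)
  new_consensus(sum(w * x$mean), w, "graybill_deal")
}

#' Mandel-Paule consensus mean
#'
#' Interlaboratory consensus estimator that admits extra between-study
#' dispersion: a between-study variance component \eqn{\tau^2 \ge 0} is
#' chosen so that the weighted dispersion statistic matches its expectation,
#' \deqn{\sum_i w_i(\tau^2)\,(\bar f_i - \hat\mu(\tau^2))^2 = k - 1,
#'       \qquad w_i(\tau^2) = \frac{1}{S_i^2/n_i + \tau^2},}
#' solved by bisection (the left side is decreasing in \eqn{\tau^2}). When
#' the statistic at \eqn{\tau^2 = 0} already falls below \eqn{k - 1} the
#' component is clamped to zero and the estimator coincides with
#' Graybill-Deal weighting. As \eqn{\tau^2 \to \infty} the weights equalise
#' and the estimator tends to the unweighted mean of the study means.
#'
#' @inheritParams overall_mean
#' @param tol absolute tolerance on the Mandel-Paule criterion; default 1e-10.
#' @param max_iter maximum bisection iterations; default 200. Running out of
#'   iterations flags `converged = FALSE` rather than raising an error.
#' @return A `consensus_mean` with `method = "mandel_paule"` plus `tau2`,
#'   `iterations` and `converged`.
#' @export
mandel_paule_mean <- function(collection, tol = 1e-10, max_iter = 200L) {
  x <- as_study_collection(collection)
  total_n(x)
  if (n_studies(x) < 2) stop("Mandel-Paule needs at least two studies")
  .require_sds(x, "mandel_paule_mean")
  k <- n_studies(x)
  v <- x$sd^2 / x$n  # within-study variance of each mean

  crit <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * x$mean) / sum(w)
    sum(w * (x$mean - mu)^2) - (k - 1)
  }

  iterations <- 0L
  converged <- TRUE
  if (crit(0) <= 0) {
    tau2 <- 0
  } else {
    lo <- 0
    hi <- 10 * max(stats::var(x$mean), max(v))
    while (crit(hi) > 0 && iterations < max_iter) {  # grow bracket if needed
      hi <- hi * 10
      iterations <- iterations + 1L
    }
    repeat {
      tau2 <- (lo + hi) / 2
      f <- crit(tau2)
      iterations <- iterations + 1L
      if (abs(f) <= tol) break
      if (iterations >= max_iter) {
        converged <- FALSE
        break
      }
      if (f > 0) lo <- tau2 else hi <- tau2
    }
  }
  w <- 1 / (v + tau2)
  w <- w / sum(w)
  out <- new_consensus(sum(w * x$mean), w, "mandel_paule")
  out$tau2 <- tau2
  out$iterations <- iterations
  out$converged <- converged
  out
}

new_consensus <- function(mean, weights, method) {
  stopifnot(abs(sum(weights) - 1) < 1e-12, all(weights >= 0))
  structure(list(mean = mean, weights = weights, method = method),
            class = "consensus_mean")
}

#' @export
print.consensus_mean <- function(x, digits = 4, ...) {
  cat("Consensus mean (", x$method, "): ",
      format(x$mean, digits = digits), "\n", sep = "")
  if (!is.null(x$tau2))
    cat("  tau2 =", format(x$tau2, digits = digits),
        " iterations =", x$iterations,
        if (!x$converged) " (NOT converged)" else "", "\n")
  cat("  weights:", paste(format(x$weights, digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Moments of a product of two random quantities
#'
#' Emission totals are products \eqn{A \times F} of activity data and an
#' emission factor, and both carry uncertainty. For the mean the exact
#' relation \eqn{E[AF] = E[A]E[F] + Cov(A, F)} is used. For the variance,
#' when \eqn{A} and \eqn{F} are independent the exact product formula
#' \deqn{Var(AF) = E[A]^2 Var(F) + E[F]^2 Var(A) + Var(A)Var(F)}
#' applies; with nonzero covariance the exact jointly-normal product
#' variance is returned,
#' \deqn{Var(AF) = E[A]^2 Var(F) + E[F]^2 Var(A) + 2 E[A] E[F] Cov(A, F)
#'       + Var(A) Var(F) + Cov(A, F)^2,}
#' which reduces to the familiar first-order error-propagation formula when
#' the two quadratic terms (small for small coefficients of variation) are
#' dropped, and to the exact independent-case formula at zero covariance.
#'
#' @param mean_a,var_a mean and variance of the activity quantity.
#' @param mean_f,var_f mean and variance of the emission factor.
#' @param covariance covariance of the two; must satisfy
#'   \eqn{|Cov| \le \sqrt{Var(A) Var(F)}}. Default 0 (independence).
#' @return List with `mean`, `variance`, `correlation` and a `method` tag
#'   (`"exact_independent"` or `"exact_bivariate_normal"`).
#' @examples
#' product_moments(2, 1, 3, 1)  # independent: mean 6, variance 4 + 9 + 1
#' @export
product_moments <- function(mean_a, var_a, mean_f, var_f, covariance = 0) {
  if (var_a < 0 || var_f < 0) stop("variances must be >= 0")
  bound <- sqrt(var_a * var_f)
  if (abs(covariance) > bound + 1e-12 * max(bound, 1))
    stop("covariance exceeds the Cauchy-Schwarz bound sqrt(var_a * var_f)")
  rho <- if (bound > 0) covariance / bound else 0
  m <- mean_a * mean_f + covariance
  if (covariance == 0) {
    v <- mean_a^2 * var_f + mean_f^2 * var_a + var_a * var_f
    method <- "exact_independent"
  } else {
    v <- mean_a^2 * var_f + mean_f^2 * var_a +
      2 * mean_a * mean_f * covariance + var_a * var_f + covariance^2
    method <- "exact_bivariate_normal"
  }
  list(mean = m, variance = max(v, 0), correlation = rho, method = method)
}
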