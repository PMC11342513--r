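#' Pool emission-factor estimates from multiple studies
#'
#' The main fitting function of the package. Given \eqn{k} study summaries
#' (sample sizes, means and standard deviations) — or the raw observations —
#' it estimates the common mean emission factor by the sample-size-weighted
#' overall mean \eqn{\bar{\bar f}}, estimates the population variance by
#' every estimator the data support (pooled \eqn{S^2_p}, between-means
#' \eqn{n S^2_m}, ANOVA \eqn{S^2_a = SST/(N-1)}), and builds Student-t and
#' chi-square confidence intervals from the selected variance estimator's
#' scaled chi-square distribution.
#'
#' The default estimator is the ANOVA one: it uses both the within-study and
#' the between-study dispersion, is unbiased under a homogeneous normal
#' population, and has the smallest sampling variance of the three (df =
#' N - 1). Select `"pooled"` when the study means are expected to differ for
#' non-random reasons (fixed group effects), or `"between_means"` when only
#' study means are available — then a common per-study `n` must be supplied,
#' and the result scales linearly with that assumption.
#'
#' @param data study summaries (a [study_collection()] or a data frame with
#'   columns `study`, `n`, `mean`, `sd`) or raw observations (a data frame
#'   with columns `study`, `value`, or a named list of numeric vectors).
#' @param n optional common sample size when summaries carry none.
#' @param estimator which variance estimator drives the intervals:
#'   `"anova"` (default), `"pooled"` or `"between_means"`.
#' @param conf_level confidence level for both intervals; default 0.95.
#' @param log_scale if `TRUE`, each study's (mean, sd) is mapped to the log
#'   scale by method-of-moments lognormal matching
#'   (\eqn{\mu_{log} = \log(m^2/\sqrt{m^2+s^2})},
#'   \eqn{\sigma^2_{log} = \log(1 + s^2/m^2)}; raw observations are simply
#'   logged) and all pooling is done there. Intervals are reported on the
#'   log scale only; the point estimate is back-transformed as
#'   \eqn{\exp(\hat\mu + S^2/2)} and reported as `natural_mean`.
#' @param n_assumed per-study size for the between-means estimator when it
#'   differs from the data's `n` (or when `n` is unknown).
#'
#' @return An object of class `ef_pool` with components `mu_hat`,
#'   `estimates` (named list of `variance_estimate`s), `estimator`,
#'   `weights` (`w1`, `w2`), `ci_mu`, `ci_sigma2`, `collection`,
#'   `conf_level`, `log_scale` and `call`. Methods: `print`, `summary`,
#'   `coef`, `confint`, `residuals`, `plot`, `simulate`.
#'
#' @examples
#' fit <- ef_pool(rice_case_study())
#' fit
#' coef(fit)
#' confint(fit)
#' @export
ef_pool <- function(data, n = NULL,
                    estimator = c("anova", "pooled", "between_means"),
                    conf_level = 0.95, log_scale = FALSE, n_assumed = NULL) {
  estimator <- match.arg(estimator)
  .check_level(conf_level)
  cl <- match.call()

  is_raw <- (is.list(data) && !is.data.frame(data) &&
               !inherits(data, "study_collection")) ||
    (is.data.frame(data) && "value" %in% names(data))
  raw <- NULL
  if (is_raw) {
    raw <- .as_raw_list(data)
    if (log_scale) {
      if (any(unlist(raw, use.names = FALSE) <= 0))
        stop("log-scale pooling needs strictly positive observations")
      raw <- lapply(raw, log)
    }
    x <- summarise_raw(raw)
  } else {
    x <- as_study_collection(data, n = n)
    # published tables often omit sample sizes; an assumed common size then
    # stands in for all of them
    if (anyNA(x$n) && !is.null(n_assumed))
      x <- as_study_collection(x, n = n_assumed)
    if (log_scale) x <- .log_moments(x)
  }

  mu_hat <- overall_mean(x)
  N <- total_n(x)
  k <- n_studies(x)

  estimates <- list()
  if (!anyNA(x$sd)) {
    estimates$pooled <- pooled_variance(x)
    estimates$anova <- if (!is.null(raw)) anova_variance_raw(raw)
                       else anova_variance(x)
  }
  bm <- tryCatch(between_means_variance(x, n_assumed), error = function(e) e)
  if (!inherits(bm, "error")) estimates$between_means <- bm

  if (is.null(estimates[[estimator]])) {
    if (estimator == "between_means") stop(conditionMessage(bm))
    stop("estimator '", estimator, "' needs a standard deviation for every study")
  }
  chosen <- estimates[[estimator]]

  structure(list(call = cl, collection = x, raw = raw, mu_hat = mu_hat,
                 estimates = estimates, estimator = estimator,
                 weights = anova_weights(x),
                 ci_mu = ci_mean(mu_hat, chosen, N, conf_level),
                 ci_sigma2 = ci_variance(chosen, conf_level),
                 conf_level = conf_level, log_scale = log_scale,
                 natural_mean = if (log_scale)
                   exp(mu_hat + chosen$value / 2) else NULL),
            class = "ef_pool")
}

# method-of-moments lognormal matching of each study summary
.log_moments <- function(x) {
  if (anyNA(x$sd)) stop("log-scale pooling needs a standard deviation per study")
  if (any(x$mean <= 0)) stop("log-scale pooling needs strictly positive means")
  cv2 <- (x$sd / x$mean)^2
  study_collection(x$study, n = x$n,
                   mean = log(x$mean / sqrt(1 + cv2)),
                   sd = sqrt(log(1 + cv2)))
}

#' @export
print.ef_pool <- function(x, digits = 4, ...) {
  chosen <- x$estimates[[x$estimator]]
  scale_lab <- if (x$log_scale) " (log scale)" else ""
  cat("Pooled emission factor", scale_lab, "\n", sep = "")
  cat(sprintf("  k = %d studies, N = %d observations\n",
              n_studies(x$collection), total_n(x$collection)))
  cat(sprintf("  mean: %s  [%s, %s] (%d%% CI, t, df = %d)\n",
              format(x$mu_hat, digits = digits),
              format(x$ci_mu$lower, digits = digits),
              format(x$ci_mu$upper, digits = digits),
              round(100 * x$conf_level), x$ci_mu$df))
  cat(sprintf("  variance (%s): %s  sd: %s\n", x$estimator,
              format(chosen$value, digits = digits),
              format(sqrt(chosen$value), digits = digits)))
  if (!is.null(x$natural_mean))
    cat("  back-transformed mean (natural scale):",
        format(x$natural_mean, digits = digits), "\n")
  invisible(x)
}

#' @export
summary.ef_pool <- function(object, ...) {
  est <- object$estimates
  tab <- data.frame(
    estimator = names(est),
    value = vapply(est, function(e) e$value, 1.0),
    df = vapply(est, function(e) e$df, 1L),
    sd = sqrt(vapply(est, function(e) e$value, 1.0)),
    row.names = NULL)
  structure(list(fit = object, estimator_table = tab), class = "summary.ef_pool")
}

#' @export
print.summary.ef_pool <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nANOVA weights: w1 =", format(x$fit$weights[["w1"]], digits = digits),
      " w2 =", format(x$fit$weights[["w2"]], digits = digits), "\n")
  cat("\nVariance estimators:\n")
  print(format(x$estimator_table, digits = digits), row.names = FALSE)
  cat(sprintf("\n%d%% CI for the population variance (df = %d): [%s, %s]\n",
              round(100 * x$fit$conf_level), x$fit$ci_sigma2$df,
              format(x$fit$ci_sigma2$lower, digits = digits),
              format(x$fit$ci_sigma2$upper, digits = digits)))
  cat("\nStudies:\n")
  print.data.frame(x$fit$collection, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ef_pool <- function(object, ...) {
  c(mu = object$mu_hat, sigma2 = object$estimates[[object$estimator]]$value)
}

#' @rdname ef_pool
#' @param object,parm,level standard [stats::confint()] arguments; `parm`
#'   selects `"mu"`, `"sigma2"` or both.
#' @param ... unused.
#' @export
confint.ef_pool <- function(object, parm = c("mu", "sigma2"), level = NULL,
                            ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  if (is.null(level)) level <- object$conf_level
  chosen <- object$estimates[[object$estimator]]
  rows <- lapply(parm, function(p) {
    ci <- if (p == "mu")
      ci_mean(object$mu_hat, chosen, total_n(object$collection), level)
    else ci_variance(chosen, level)
    c(ci$lower, ci$upper)
  })
  out <- do.call(rbind, rows)
  a <- (1 - level) / 2
  dimnames(out) <- list(parm, sprintf("%.1f %%", 100 * c(a, 1 - a)))
  out
}

#' @export
residuals.ef_pool <- function(object, ...) {
  stats::setNames(object$collection$mean - object$mu_hat,
                  object$collection$study)
}

#' @export
plot.ef_pool <- function(x, ...) {
  d <- x$collection
  has_sd <- !anyNA(d$sd)
  ylim <- range(if (has_sd) c(d$mean - d$sd, d$mean + d$sd) else d$mean,
                x$ci_mu$lower, x$ci_mu$upper)
  at <- seq_len(nrow(d))
  graphics::plot(at, d$mean, xaxt = "n", xlab = "study",
                 ylab = "emission factor", ylim = ylim, pch = 19,
                 xlim = c(0.5, nrow(d) + 0.5), ...)
  graphics::axis(1, at = at, labels = d$study)
  if (has_sd) graphics::segments(at, d$mean - d$sd, at, d$mean + d$sd)
  graphics::abline(h = x$mu_hat, lty = 1)
  graphics::abline(h = c(x$ci_mu$lower, x$ci_mu$upper), lty = 3)
  invisible(x)
}

#' @rdname ef_pool
#' @param nsim number of collections to simulate.
#' @param seed optional seed, as in [stats::simulate()].
#' @export
simulate.ef_pool <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$collection
  s2 <- object$estimates[[object$estimator]]$value
  lapply(seq_len(nsim), function(i) {
    raw <- lapply(stats::setNames(d$n, d$study), function(ni)
      stats::rnorm(ni, object$mu_hat, sqrt(s2)))
    summarise_raw(raw)
  })
}

#' Machine-readable pooling report
#'
#' Flattens an [ef_pool()] fit into a plain list (suitable for JSON) echoing
#' the per-study table, all variance estimates, the ANOVA weights, both
#' confidence intervals, and provenance notes (assumed sample sizes, scale).
#' Serialization is deterministic: identical fits give byte-identical files.
#'
#' @param fit an `ef_pool` object.
#' @param path optional file path; when given the report is written as JSON.
#' @return The report list (invisibly, when `path` is given).
#' @export
pool_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "ef_pool"))
  rep <- list(
    mu_hat = fit$mu_hat,
    estimator = fit$estimator,
    variance_estimates = lapply(fit$estimates, function(e)
      list(value = e$value, df = e$df)),
    weights = as.list(fit$weights),
    conf_level = fit$conf_level,
    ci_mu = list(lower = fit$ci_mu$lower, upper = fit$ci_mu$upper),
    ci_sigma2 = list(lower = fit$ci_sigma2$lower, upper = fit$ci_sigma2$upper),
    log_scale = fit$log_scale,
    natural_mean = fit$natural_mean,
    studies = lapply(seq_len(nrow(fit$collection)), function(i)
      list(study = fit$collection$study[i],
           n = fit$collection$n[i],
           mean = fit$collection$mean[i],
           sd = if (is.na(fit$collection$sd[i])) NULL else fit$collection$sd[i]))
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
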