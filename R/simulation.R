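#' Define a Monte Carlo scenario
#'
#' A scenario fixes the study design and population for a simulation run:
#' \eqn{k} independent groups of \eqn{n} i.i.d. draws from a normal
#' population with mean `mu` and variance `sigma2`. The defaults reproduce
#' the benchmark design used throughout this package's validation: 4 groups
#' of 5 standard-normal observations, 1000 replications.
#'
#' @param k number of groups (studies); at least 2 for intergroup estimators.
#' @param n observations per group; a single value or one per group.
#' @param mu population mean.
#' @param sigma2 population variance, strictly positive.
#' @param replications Monte Carlo replications, at least 1.
#' @param seed integer seed for the single generator driving a run.
#' @param n_assumed the per-group size fed to the between-means estimator;
#'   defaults to the true common `n` (in practice it would be unknown, and a
#'   wrong guess scales that estimator proportionally).
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(k = 4L, n = 5L, mu = 0, sigma2 = 1,
                         replications = 1000L, seed = 20240205L,
                         n_assumed = NULL) {
  if (length(n) == 1L) n <- rep(n, k)
  stopifnot(k >= 1, length(n) == k, all(n >= 1), replications >= 1)
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  if (is.null(n_assumed)) {
    n_assumed <- if (length(unique(n)) == 1L) n[1] else NA_integer_
  }
  structure(list(k = as.integer(k), n = as.integer(n), mu = mu,
                 sigma2 = sigma2, replications = as.integer(replications),
                 seed = as.integer(seed), n_assumed = n_assumed),
            class = "sim_scenario")
}

#' Draw one synthetic collection of raw studies
#'
#' Generates `scenario$k` groups of i.i.d. normal(\eqn{\mu}, \eqn{\sigma^2})
#' observations. Uses the current RNG state unless `seed` is given, so a
#' harness that sets the seed once obtains an independent stream of
#' collections; passing the same `seed` twice yields identical data.
#'
#' @param scenario a [sim_scenario()].
#' @param seed optional seed applied just before drawing.
#' @return Named list of numeric vectors (one study each), suitable for
#'   [anova_variance_raw()] or [summarise_raw()].
#' @export
generate_collection <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  obs <- stats::rnorm(sum(scenario$n), scenario$mu, sqrt(scenario$sigma2))
  stats::setNames(split(obs, rep(seq_len(scenario$k), scenario$n)),
                  paste0("g", seq_len(scenario$k)))
}

# all three variance estimates for one simulated collection
.estimates_once <- function(raw, n_assumed) {
  summ <- summarise_raw(raw)
  c(pooled = pooled_variance(summ)$value,
    anova = anova_variance(summ)$value,
    between_means = between_means_variance(summ, n_assumed)$value)
}

#' Monte Carlo comparison of the three variance estimators
#'
#' For each replication, draws a collection under the scenario, computes the
#' pooled, ANOVA and between-means variance estimates, and summarises their
#' empirical mean and standard deviation next to the theoretical sampling
#' standard deviation \eqn{\sqrt{2\sigma^4/df}}. All three estimators are
#' unbiased; their spreads differ, with the ANOVA estimator the tightest and
#' the between-means estimator by far the loosest (its distribution also
#' shows the heaviest right tail, having the fewest degrees of freedom).
#'
#' @param scenario a [sim_scenario()].
#' @return A `sim_report` with a `summary` data frame (one row per
#'   estimator: `average`, `sd`, `theoretical_sd`) and the full `estimates`
#'   matrix (replications x 3) for histograms and tail diagnostics.
#' @examples
#' \donttest{
#' run_comparison(sim_scenario(replications = 200, seed = 1))
#' }
#' @export
run_comparison <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (scenario$k < 2) stop("estimator comparison needs k >= 2")
  set.seed(scenario$seed)
  est <- t(vapply(seq_len(scenario$replications),
                  function(i) .estimates_once(generate_collection(scenario),
                                              scenario$n_assumed),
                  c(pooled = 0, anova = 0, between_means = 0)))
  design <- study_collection(paste0("g", seq_len(scenario$k)),
                             n = scenario$n,
                             mean = rep(0, scenario$k))
  theo <- vapply(colnames(est), estimator_sampling_variance,
                 numeric(1), sigma2 = scenario$sigma2, collection = design)
  summary <- data.frame(estimator = colnames(est),
                        average = colMeans(est),
                        sd = apply(est, 2, stats::sd),
                        theoretical_sd = sqrt(theo),
                        row.names = NULL)
  structure(list(scenario = scenario, summary = summary, estimates = est),
            class = "sim_report")
}

#' Monte Carlo coverage of the confidence intervals
#'
#' Checks, by simulation, that the Student-t interval for the mean and the
#' chi-square interval for the variance (both built on the ANOVA estimator,
#' df = N - 1) attain their nominal coverage under the scenario's normal
#' population.
#'
#' @param scenario a [sim_scenario()].
#' @param level nominal confidence level; default 0.95.
#' @return A `sim_report` whose `summary` holds one row per parameter with
#'   the empirical `coverage` and its binomial Monte Carlo standard error.
#' @export
run_coverage <- function(scenario, level = 0.95) {
  stopifnot(inherits(scenario, "sim_scenario"))
  .check_level(level)
  set.seed(scenario$seed)
  R <- scenario$replications
  N <- sum(scenario$n)
  hit <- matrix(FALSE, R, 2, dimnames = list(NULL, c("mu", "sigma2")))
  for (i in seq_len(R)) {
    raw <- generate_collection(scenario)
    va <- anova_variance_raw(raw)
    mu_hat <- mean(unlist(raw, use.names = FALSE))
    cim <- ci_mean(mu_hat, va, N, level)
    civ <- ci_variance(va, level)
    hit[i, 1] <- cim$lower <= scenario$mu && scenario$mu <= cim$upper
    hit[i, 2] <- civ$lower <= scenario$sigma2 && scenario$sigma2 <= civ$upper
  }
  cov <- colMeans(hit)
  summary <- data.frame(parameter = colnames(hit), level = level,
                        coverage = cov,
                        mc_se = sqrt(cov * (1 - cov) / R),
                        row.names = NULL)
  structure(list(scenario = scenario, summary = summary, hits = hit),
            class = "sim_report")
}

#' @export
print.sim_report <- function(x, digits = 4, ...) {
  s <- x$scenario
  cat(sprintf("Monte Carlo report: k = %d, n = %s, mu = %g, sigma2 = %g, R = %d, seed = %d\n",
              s$k, paste(unique(s$n), collapse = "/"), s$mu, s$sigma2,
              s$replications, s$seed))
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Histograms of the simulated variance estimates
#'
#' Side-by-side histograms of the pooled, ANOVA and between-means estimates
#' from a [run_comparison()] report, on a common x-range capped at the 99.5th
#' percentile so the between-means estimator's long right tail does not
#' flatten the other panels.
#'
#' @param x a `sim_report` from [run_comparison()].
#' @param breaks number of equal-width bins; default 30.
#' @param ... passed to [graphics::hist()].
#' @return Invisibly, `x`.
#' @export
plot.sim_report <- function(x, breaks = 30, ...) {
  if (is.null(x$estimates)) stop("plotting needs a run_comparison() report")
  est <- x$estimates
  xmax <- stats::quantile(est, 0.995)
  brk <- seq(0, xmax, length.out = breaks + 1)
  old <- graphics::par(mfrow = c(1, ncol(est)))
  on.exit(graphics::par(old))
  for (j in colnames(est)) {
    v <- pmin(est[, j], xmax)
    graphics::hist(v, breaks = brk, main = j, xlab = "variance estimate", ...)
    graphics::abline(v = x$scenario$sigma2, lty = 2)
  }
  invisible(x)
}
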