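test_that("inverse-variance weighting reduces to the overall mean under equal variances", {
  d <- study_collection(letters[1:3], n = c(4, 9, 2), mean = c(1, 5, 3),
                        sd = c(1, 1, 1))
  iv <- inverse_variance_mean(d, variances = rep(2.5, 3))
  expect_equal(iv$mean, overall_mean(d))
  expect_equal(iv$weights, d$n / sum(d$n))

  two <- study_collection(c("a", "b"), n = c(1, 1), mean = c(0, 5))
  expect_equal(inverse_variance_mean(two, c(1, 4))$mean, 1.0)

  # permutation invariance
  perm <- study_collection(c("b", "a"), n = c(1, 1), mean = c(5, 0))
  expect_equal(inverse_variance_mean(perm, c(4, 1))$mean, 1.0)

  expect_error(inverse_variance_mean(two, c(1, -1)), "strictly positive")
  expect_error(inverse_variance_mean(two, c(1, 1e-20)),
               "indistinguishable from zero")
})

test_that("inverse-variance mean agrees with metafor's fixed-effect fit", {
  skip_if_not_installed("metafor")
  set.seed(21)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    d <- study_collection(paste0("s", 1:k), n = sample(5:20, k, TRUE),
                          mean = rnorm(k, 10, 2))
    v <- runif(k, 0.5, 3)
    ours <- inverse_variance_mean(d, v)$mean
    ref <- metafor::rma(yi = d$mean, vi = v / d$n, method = "FE")
    expect_equal(ours, as.numeric(ref$beta), tolerance = 1e-10)
  }
})

test_that("Graybill-Deal weights are plug-in inverse variances", {
  eq <- study_collection(letters[1:3], n = 8, mean = c(1, 2, 6),
                         sd = rep(2, 3))
  expect_equal(graybill_deal_mean(eq)$mean, 3)

  d <- study_collection(c("a", "b"), n = c(10, 10), mean = c(0, 5),
                        sd = sqrt(c(1, 4)))
  # hand computation: weights proportional to (10, 2.5) -> (0.8, 0.2)
  gd <- graybill_deal_mean(d)
  expect_equal(gd$weights, c(0.8, 0.2))
  expect_equal(gd$mean, 1.0)

  perm <- study_collection(c("b", "a"), n = c(10, 10), mean = c(5, 0),
                           sd = sqrt(c(4, 1)))
  expect_equal(graybill_deal_mean(perm)$mean, 1.0)

  z <- study_collection(c("a", "b"), n = 5, mean = c(0, 1), sd = c(0, 1))
  expect_error(graybill_deal_mean(z), "zero sample variance")
})

test_that("consensus means are convex combinations of the study means", {
  set.seed(31)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    d <- study_collection(paste0("s", 1:k), n = sample(2:20, k, TRUE),
                          mean = rnorm(k, 0, 5), sd = runif(k, 0.2, 3))
    for (m in list(graybill_deal_mean(d),
                   inverse_variance_mean(d, runif(k, 0.5, 4)),
                   mandel_paule_mean(d))) {
      expect_gte(m$mean, min(d$mean))
      expect_lte(m$mean, max(d$mean))
      expect_equal(sum(m$weights), 1)
    }
  }
})

test_that("Mandel-Paule solves the dispersion criterion and handles extremes", {
  # identical means: no between-study component
  same <- study_collection(letters[1:3], n = 10, mean = rep(4, 3),
                           sd = c(1, 2, 3))
  mp0 <- mandel_paule_mean(same)
  expect_equal(mp0$tau2, 0)
  expect_equal(mp0$mean, 4)

  # toy spread-out summaries: criterion satisfied at the returned tau2
  d <- study_collection(letters[1:3], n = 10, mean = c(1, 2, 9),
                        sd = c(1, 1, 1))
  mp <- mandel_paule_mean(d)
  expect_true(mp$converged)
  w <- 1 / (d$sd^2 / d$n + mp$tau2)
  mu <- sum(w * d$mean) / sum(w)
  expect_equal(sum(w * (d$mean - mu)^2), 2, tolerance = 1e-8)

  # independent root-finding oracle (Brent via uniroot) on the same criterion
  crit <- function(tau2) {
    w <- 1 / (d$sd^2 / d$n + tau2)
    mu <- sum(w * d$mean) / sum(w)
    sum(w * (d$mean - mu)^2) - 2
  }
  oracle <- uniroot(crit, c(0, 1000), tol = 1e-12)$root
  expect_lt(abs(mp$tau2 - oracle), 1e-8)

  # tau2 = 0 coincides with Graybill-Deal weighting
  near <- study_collection(letters[1:3], n = 10, mean = c(4, 4.01, 3.99),
                           sd = c(1, 1, 1))
  mpn <- mandel_paule_mean(near)
  expect_equal(mpn$tau2, 0)
  expect_equal(mpn$weights, graybill_deal_mean(near)$weights)

  # huge between-study spread: weights equalise, mean -> unweighted average
  far <- study_collection(letters[1:3], n = c(5, 10, 20),
                          mean = c(0, 500, 1000), sd = c(1, 1, 1))
  mpf <- mandel_paule_mean(far)
  expect_equal(mpf$weights, rep(1 / 3, 3), tolerance = 1e-3)
  expect_equal(mpf$mean, 500, tolerance = 0.5)
})

test_that("product moments are exact for independent and jointly normal factors", {
  pm <- product_moments(2, 1, 3, 1)
  expect_equal(pm$mean, 6)
  # exact independent identity: E[A^2]E[F^2] - (E[A]E[F])^2
  expect_equal(pm$variance, (4 + 1) * (9 + 1) - 36)

  # a constant factor scales variance quadratically
  expect_equal(product_moments(5, 0.3, 7, 0)$variance, 49 * 0.3)

  expect_error(product_moments(0, 1, 0, 1, covariance = 1.5),
               "Cauchy-Schwarz")

  # Monte Carlo oracle: bivariate normal mu = (2, 3), unit variances, rho = 0.5
  set.seed(99)
  n <- 1e6
  a <- rnorm(n)
  f <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  a <- 2 + a; f <- 3 + f
  prod <- a * f
  pm2 <- product_moments(2, 1, 3, 1, covariance = 0.5)
  se_mean <- sd(prod) / sqrt(n)
  expect_equal(pm2$mean, mean(prod), tolerance = 3 * se_mean / abs(pm2$mean))
  v_hat <- var(prod)
  se_var <- sqrt((mean((prod - mean(prod))^4) - v_hat^2) / n)
  expect_lt(abs(pm2$variance - v_hat), 3 * se_var)
  expect_equal(pm2$correlation, 0.5)
})
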