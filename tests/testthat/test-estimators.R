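test_that("overall mean is the sample-size weighted average of study means", {
  expect_equal(round(overall_mean(case_summaries()), 1), 25.6)
  one <- study_collection("a", n = 5, mean = 7.3, sd = 1)
  expect_equal(overall_mean(one), 7.3)
  two <- study_collection(c("a", "b"), n = c(2, 3), mean = c(1, 2))
  expect_equal(overall_mean(two), 1.6)
  expect_error(study_collection(character(), mean = numeric()), "at least one")
  noN <- study_collection(c("a", "b"), mean = c(1, 2))
  expect_error(overall_mean(noN), "unknown sample size for study a")
})

test_that("pooled variance weights sample variances by their df", {
  pv <- pooled_variance(case_summaries())
  expect_equal(round(pv$value, 2), 0.82)
  expect_equal(pv$df, 27)

  const <- study_collection(c("a", "b"), n = c(4, 9), mean = c(0, 5),
                            sd = c(1.7, 1.7))
  expect_equal(pooled_variance(const)$value, 1.7^2)

  two <- study_collection(c("a", "b"), n = c(3, 5), mean = c(0, 0),
                          sd = sqrt(c(2, 1)))
  expect_equal(pooled_variance(two)$value, (2 * 2 + 4 * 1) / 6)
  expect_equal(pooled_variance(two)$df, 6)

  expect_error(
    study_collection(c("a", "b"), n = 1, mean = c(0, 1), sd = c(1, 1)),
    "single observation")
  nosd <- study_collection(c("a", "b"), n = 5, mean = c(0, 1))
  expect_error(pooled_variance(nosd), "standard deviation for every study")
})

test_that("between-means estimator scales the variance of the means by n", {
  bm <- between_means_variance(case_summaries())
  expect_equal(round(bm$value, 2), 180.12)
  expect_equal(bm$df, 2)

  same <- study_collection(letters[1:3], n = 7, mean = rep(2.2, 3),
                           sd = rep(1, 3))
  expect_equal(between_means_variance(same)$value, 0)

  pair <- study_collection(c("a", "b"), mean = c(0, 2))
  expect_equal(between_means_variance(pair, n_assumed = 4)$value, 8)

  expect_error(between_means_variance(
    study_collection("a", n = 5, mean = 1)), "at least two studies")
  expect_error(between_means_variance(pair, n_assumed = 0), "positive integer")
  expect_error(between_means_variance(pair), "supply n_assumed")
})

test_that("ANOVA weights are the df shares and always sum to one", {
  w <- anova_weights(case_summaries())
  expect_equal(unname(w), c(27 / 29, 2 / 29))
  expect_equal(round(unname(w), 2), c(0.93, 0.07))

  w1 <- anova_weights(study_collection("a", n = 6, mean = 0, sd = 1))
  expect_equal(unname(w1), c(1, 0))

  set.seed(11)
  for (i in 1:25) {
    k <- sample(1:8, 1)
    d <- study_collection(paste0("s", 1:k), n = sample(2:40, k, TRUE),
                          mean = rnorm(k))
    expect_identical(sum(anova_weights(d)), 1)
  }
  expect_error(anova_weights(study_collection("a", n = 1, mean = 0)),
               "single observation")
})

test_that("summary- and raw-data routes to the ANOVA estimator agree", {
  sa <- anova_variance(case_summaries())
  expect_equal(round(sa$value, 2), 13.19)
  expect_equal(sa$df, 29)

  # hand-checkable: groups {1,2,3} and {4,5,6}
  raw <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  vr <- anova_variance_raw(raw)
  expect_equal(vr$sums$sst, 17.5)
  expect_equal(vr$sums$ssw, 4)
  expect_equal(vr$sums$ssb, 13.5)
  expect_equal(vr$value, 3.5)
  expect_equal(vr$df, 5)
  expect_equal(anova_variance(summarise_raw(raw))$value, 3.5)

  # k = 1 collapses to the single sample variance
  one <- study_collection("a", n = 9, mean = 4, sd = 1.3)
  expect_equal(anova_variance(one)$value, 1.3^2)

  # constant data
  flat <- anova_variance_raw(list(a = rep(2, 3), b = rep(2, 4)))
  expect_equal(flat$value, 0)
  expect_equal(unlist(flat$sums), c(sst = 0, ssw = 0, ssb = 0))

  expect_error(anova_variance_raw(list(a = 1)), "fewer than two")
})

test_that("law of total variance holds and the two routes agree on random data", {
  set.seed(101)
  for (i in 1:200) {
    raw <- random_raw()
    vr <- anova_variance_raw(raw)
    expect_lt(abs(vr$sums$sst - (vr$sums$ssw + vr$sums$ssb)),
              1e-9 * max(vr$sums$sst, 1))
    vs <- anova_variance(summarise_raw(raw))
    expect_lt(abs(vs$value - vr$value), 1e-10 * max(vr$value, 1e-10))
    expect_equal(vs$df, vr$df)
  }
})

test_that("with equal n the weighted combination reproduces SST/(N-1)", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- sample(3:10, 1)
    raw <- lapply(seq_len(k), function(j) rnorm(n, rnorm(1, 0, 2)))
    names(raw) <- paste0("g", 1:k)
    s <- summarise_raw(raw)
    w <- anova_weights(s)
    combo <- w[["w1"]] * pooled_variance(s)$value +
      w[["w2"]] * between_means_variance(s)$value
    expect_equal(combo, anova_variance_raw(raw)$value)
  }
})

test_that("theoretical sampling variances are 2 sigma^4 / df and ordered", {
  d <- study_collection(letters[1:4], n = 5, mean = rep(0, 4), sd = rep(1, 4))
  expect_equal(estimator_sampling_variance("pooled", 1, d), 2 / 16)
  expect_equal(estimator_sampling_variance("between_means", 1, d), 2 / 3)
  expect_equal(estimator_sampling_variance("anova", 1, d), 2 / 19)

  # sigma^4 homogeneity
  expect_equal(estimator_sampling_variance("anova", 3, d),
               9 * estimator_sampling_variance("anova", 1, d))

  set.seed(12)
  for (i in 1:100) {
    k <- sample(2:8, 1)
    dd <- study_collection(paste0("s", 1:k), n = sample(2:30, k, TRUE),
                           mean = rnorm(k), sd = rep(1, k))
    s2 <- runif(1, 0.1, 5)
    va <- estimator_sampling_variance("anova", s2, dd)
    vp <- estimator_sampling_variance("pooled", s2, dd)
    vm <- estimator_sampling_variance("between_means", s2, dd)
    expect_true(va <= vp && vp <= vm)
  }
  expect_error(estimator_sampling_variance("anova", -1, d), "must be > 0")
  expect_error(estimator_sampling_variance("median", 1, d), "'arg'")
})
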