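---
title: "Pooling emission-factor estimates: model, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling emission-factor estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efpool)
```

## The problem

Bottom-up greenhouse-gas accounting multiplies activity data $A$ by an
emission factor $F$, and the factor is usually the weak link: published
estimates of the same factor — each a sample size $n_i$, mean $\bar f_i$
and standard deviation $S_i$ from an independent field study — routinely
disagree by far more than their within-study spreads suggest. `efpool`
combines $k$ such summaries into one point estimate of the mean emission
factor with a defensible confidence interval, treating the studies as
independent samples from a single homogeneous normal population
$F \sim N(\mu, \sigma^2)$.

That homogeneity assumption is the model: every difference between study
means is attributed to sampling variation from the one population. When it
is untenable — different seasons, soils or measurement protocols — the
pooled standard deviation is large and should be read as a warning, not as
precision.

## Estimators

**Mean.** $\hat\mu = \bar{\bar f} = \sum n_i \bar f_i / N$ with
$N = \sum n_i$: sample-size weights, not inverse-variance weights. Reported
sample variances of emission factors are sometimes modelled or expert
numbers rather than experimental ones, and a variance reported near zero
would dominate inverse-variance weighting; size weights are immune to that
failure mode. The classical alternatives are still provided for
comparison: `inverse_variance_mean()` (known variances),
`graybill_deal_mean()` (plug-in $n_i/S_i^2$ weights) and
`mandel_paule_mean()` (an extra between-study component $\tau^2$ solved
from the dispersion criterion $\sum w_i(\tau^2)(\bar f_i - \hat\mu)^2 =
k-1$). Their formulations are the literature-standard ones.

**Variance.** Three unbiased estimators of $\sigma^2$, all scaled
chi-square under the model, differing only in degrees of freedom:

| estimator | formula | df | uses |
|---|---|---|---|
| pooled $S^2_p$ | $\sum(n_i-1)S_i^2 / \sum(n_i-1)$ | $\sum(n_i-1)$ | within-study spread only |
| between-means $nS^2_m$ | $n \cdot \mathrm{var}(\bar f_1,\dots,\bar f_k)$ | $k-1$ | study means only (common $n$ required) |
| ANOVA $S^2_a$ | $w_1 S^2_p + w_2\, nS^2_m$ | $N-1$ | both |

With $w_1 = \sum(n_i-1)/(N-1)$ and $w_2 = (k-1)/(N-1)$ — the
degrees-of-freedom shares of the within and between sums of squares — the
combination collapses, by the law of total variance $SST = SSW + SSB$, to
the total sample variance $S^2_a = SST/(N-1)$ that the raw observations
would give. That identity is what buys the distribution result: $(N-1)
S^2_a/\sigma^2 \sim \chi^2_{N-1}$, so $S^2_a$ supports exact intervals,
and its sampling variance $2\sigma^4/(N-1)$ is the smallest of the three
($2\sigma^4/df$ in each case, and $N-1 \ge \sum(n_i-1) \ge k-1$ always).

**Intervals.** `ci_mean()` is the Student-t interval
$\hat\mu \pm t_{df,\alpha/2}\, s/\sqrt N$; `ci_variance()` the equal-tail
chi-square interval $[df\,S^2/\chi^2_{1-\alpha/2},\; df\,S^2/\chi^2_{\alpha/2}]$.
Both take their df from the variance estimator in use, so a tighter
estimator yields a tighter mean interval. Only two-sided equal-tail
intervals are provided.

## Design choices where the design was open

* **Unequal sample sizes.** The between-means estimator is defined only
  for a common $n$; it is kept in exactly that form (equally-weighted
  grand mean, scale factor `n_assumed`). The ANOVA estimator, however, is
  computed from the general sums $SSW = \sum(n_i-1)S_i^2$ and
  $SSB = \sum n_i(\bar f_i - \bar{\bar f})^2$ with the $n_i$-weighted
  grand mean, which keeps $S^2_a = SST/(N-1)$ exact for any size pattern.
  With equal sizes the two routes coincide (tested to machine precision).
* **Studies with $n_i = 1$** are accepted for the overall mean but
  rejected, with a named-study error, by every estimator that needs a
  within-study variance: a single observation has no sample standard
  deviation. A *reported* sd of exactly zero is a legal value for the
  pooled/ANOVA estimators, but inverse-variance weighting rejects
  variances below $10^{-12}\times$ the median as erroneous near-zero
  reports that would swallow all the weight.
* **Mandel–Paule root finding.** The criterion is monotone decreasing in
  $\tau^2$, so plain bisection is used (criterion tolerance $10^{-10}$,
  cap 200 iterations, bracket $[0,\ 10\max(\mathrm{var}(\bar f_i),
  \max S_i^2/n_i)]$ grown tenfold if needed). Non-convergence is flagged,
  not thrown. Tests compare the root against `uniroot()` as an
  independent solver.
* **Product moments.** For emissions $A \times F$ the mean uses the exact
  relation $E[AF] = E[A]E[F] + \mathrm{Cov}$. The variance uses the exact
  independent-case product formula at zero covariance and the exact
  jointly-normal formula otherwise; dropping its two quadratic terms
  recovers the familiar first-order propagation formula, so the reported
  value is never below the first-order one.
* **Log-scale option.** For factors better modelled as lognormal,
  `ef_pool(..., log_scale = TRUE)` maps each summary to the log scale by
  method-of-moments matching ($\mu_{\log} = \log(m^2/\sqrt{m^2+s^2})$,
  $\sigma^2_{\log} = \log(1+s^2/m^2)$), pools there, and back-transforms
  only the point estimate, as $\exp(\hat\mu + S^2/2)$ so that a single
  study round-trips exactly. Intervals are reported on the log scale
  only: no exact natural-scale interval theory is attempted.
* **Rounding.** All chained results are computed from unrounded
  intermediates and rounded only for display; rounding the converted site
  summaries first would visibly shift the between-means estimate.

## What the simulations emulate — and what they do not

`sim_scenario()` draws $k$ groups of $n$ i.i.d. $N(\mu, \sigma^2)$
observations — the model's ideal world. The package default benchmark is
4 groups of 5 standard-normal draws; `run_comparison()` at 1000
replications confirms all three estimators are unbiased and that their
empirical spreads order as the theory says
($\sqrt{2/19} \approx 0.324 < \sqrt{2/16} \approx 0.354 < \sqrt{2/3}
\approx 0.816$ at $\sigma^2=1$), with the between-means histogram showing
the heaviest right tail. `run_coverage()` at 2000 replications confirms
95% intervals for both $\mu$ and $\sigma^2$ cover at their nominal rate.
Replication counts of 1000–5000 keep the whole suite in seconds on a
single core while leaving Monte Carlo error well below the effects being
checked; tolerances are 4 Monte Carlo standard errors for averages and
10% for spread ratios.

These simulations contain no outliers, no correlation between studies, no
heterogeneity of true means or variances, and no non-normality. Passing
them therefore validates the arithmetic and the distribution theory, not
the applicability of the homogeneity assumption to any particular set of
field studies. The single seeded generator (default seed 20240205) makes
every report bit-reproducible; averages such as 1.0017/1.0055/1.0258 from
other implementations of the same benchmark are reproducible in
distribution, not digit-for-digit, since they depend on the stream.

## The case study

`rice_case_study()` ships the field table behind the worked example:
three rice-paddy sites near Huê, central Vietnam, early 2018 season,
closed-chamber CH₄ fluxes (Vo et al. 2018), 10 sampling dates per site.
Daily areal rates convert to kg CH₄ per ton of rice by
$\times$ days $/$ yield — a linear unit change, so sds rescale by the
same constant. The per-site sample size $n_i = 10$ is recorded in the
fixture from the sampling design (10 dates per season); the printed table
itself does not restate it.

```{r case}
fit <- ef_pool(rice_case_study())
summary(fit)
```

The three site means disagree far beyond their within-site spreads, so
the pooled variance (0.82) alone would be wildly overconfident while the
between-means estimator (180.12) discards the within-site information;
their df-weighted combination gives $S^2_a = 13.19$, i.e. an emission
factor of $25.6 \pm 3.6$ kg CH₄ per ton.

## Known limitations

Correlated studies, outlier detection, robust consensus means, and exact
interval theory for non-normal populations are all out of scope; under
non-normality the point estimates remain sensible but the t and
chi-square interval distributions no longer hold. The between-means
estimator is only as good as the assumed $n$ — it scales linearly with
it — and should be a last resort when only means are available.
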