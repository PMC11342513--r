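# Table of field measurements for the Vietnamese rice CH4 case study
# (three neighbouring sites, early 2018 season, closed-chamber fluxes).
case_field_table <- function() {
  data.frame(site = c("C2", "C3", "C4"),
             daily_mean = c(1.444, 1.948, 1.853),
             daily_sd = c(0.058, 0.019, 0.088),
             period_days = c(109, 110, 108),
             yield_t_ha = c(7.6, 7.5, 7.3))
}

case_summaries <- function() convert_units(case_field_table(), n = 10)

# random raw dataset: k groups with varying sizes, heterogeneous means
random_raw <- function(k = sample(2:6, 1), n_range = 2:12,
                       mu = 0, sigma = 1, spread = 1) {
  ni <- sample(n_range, k, replace = TRUE)
  centers <- stats::rnorm(k, mu, spread)
  raw <- lapply(seq_len(k), function(i) stats::rnorm(ni[i], centers[i], sigma))
  names(raw) <- paste0("g", seq_len(k))
  raw
}
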