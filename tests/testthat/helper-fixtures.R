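# Shared fixtures and independent oracles for the test suite.

# random strictly-decreasing cumulative DVH on a uniform grid
random_cdvh <- function(n_edges = 30, max_dose = 60, total_volume = 100,
                        scale = "physical") {
  grid <- seq(0, max_dose, length.out = n_edges)
  vol <- total_volume * c(1, sort(stats::runif(n_edges - 1), decreasing = TRUE))
  cdvh(grid, vol, scale = scale)
}

# random differential DVH (positive volumes, distinct doses)
random_ddvh <- function(n_bins = 25, max_dose = 80, total_volume = 50,
                        scale = "physical") {
  dose <- sort(stats::runif(n_bins, 0.1, max_dose))
  vol <- stats::runif(n_bins, 0.05, 1)
  vol <- vol / sum(vol) * total_volume
  ddvh(dose, vol, scale = scale)
}

uniform_ddvh <- function(dose, volume = 10, scale = "EQD2", n_bins = 1) {
  ddvh(rep(dose, n_bins), rep(volume / n_bins, n_bins),
       total_volume = volume, scale = scale)
}

# dense-trapezoid oracle for the Webb-Nahum radiosensitivity integral,
# independent of the Gauss-Legendre path in the package
wn_trapezoid_oracle <- function(ddvh_eqd2, params, n_nodes = 1e5) {
  mu <- params$alpha_mean
  sg <- params$alpha_sd
  rho <- params$clonogen_density
  lo <- max(0, mu - 6 * sg)
  hi <- mu + 6 * sg
  a <- seq(lo, hi, length.out = n_nodes)
  s <- vapply(a, function(ai) {
    sum(ddvh_eqd2$volume * exp(-ai * ddvh_eqd2$dose))
  }, 0)
  f <- stats::dnorm(a, mu, sg) * exp(-rho * s)
  z <- stats::pnorm(hi, mu, sg) - stats::pnorm(lo, mu, sg)
  h <- a[2L] - a[1L]
  (sum(f) - (f[1L] + f[n_nodes]) / 2) * h / z
}

# exhaustive signed-rank two-sided p-value by enumerating all 2^n sign
# assignments (no zeros, no tied absolute differences assumed)
signed_rank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  combos <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(combos %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# minimal cohort_result carrying one metric for two or more schemes,
# used to exercise wilcoxon_pairwise directly on constructed paired data
paired_result <- function(values_by_scheme, metric = "tcp_median") {
  entries <- do.call(rbind, lapply(names(values_by_scheme), function(s) {
    v <- values_by_scheme[[s]]
    data.frame(
      patient_id = sprintf("P%02d", seq_along(v)), scheme = s,
      metric = metric, value = v, stringsAsFactors = FALSE
    )
  }))
  structure(list(entries = entries), class = "cohort_result")
}

# closed-form mean dose of a midpoint-differenced truncated exponential
# cumulative DVH on a uniform grid (the generator's lung shape)
exp_dvh_mean_oracle <- function(k, h, n) {
  q <- exp(-h / k)
  sum_iq <- q * (1 - n * q^(n - 1) + (n - 1) * q^n) / (1 - q)^2
  (1 - q) * h * sum_iq + (h / 2) * (1 - q^n) + n * h * q^n
}
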