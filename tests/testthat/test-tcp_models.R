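test_that("Martel response anchors at D50 and evaluates the log-logistic", {
  expect_equal(martel_dose_response(84.5), 0.5)
  expect_equal(martel_dose_response(0), 0)
  expect_equal(martel_dose_response(169), 1 / (1 + 2^-6), tolerance = 1e-12)
  expect_error(martel_dose_response(-1), ">= 0")
})

test_that("bin combination is the volume-weighted geometric mean", {
  u <- uniform_ddvh(70)
  expect_equal(combine_bins(function(d) martel_dose_response(d), u),
               martel_dose_response(70))
  # cold spot annihilates control
  cold <- ddvh(c(0, 90), c(1, 9), scale = "EQD2")
  expect_equal(tcp_martel(cold) == 0, TRUE)
  # two equal-volume bins with responses 0.9 and 0.4
  two <- ddvh(c(40, 60), c(5, 5), scale = "EQD2")
  expect_equal(combine_bins(function(d) ifelse(d < 50, 0.9, 0.4), two), 0.6)
  # constant response passes through unchanged
  expect_equal(combine_bins(function(d) rep(0.73, length(d)),
                            random_ddvh(scale = "EQD2")), 0.73)
})

test_that("Fenwick TCP anchors at D50 and penalizes volume", {
  u <- uniform_ddvh(84.6)
  expect_equal(tcp_fenwick(u, 4.9), 0.5, tolerance = 1e-12)
  hot <- uniform_ddvh(100)
  expect_equal(tcp_fenwick(hot, 4.9),
               pnorm((100 - 84.6) / (0.329 * 84.6)), tolerance = 1e-12)
  expect_lt(tcp_fenwick(hot, 49), tcp_fenwick(hot, 4.9))
  expect_error(tcp_fenwick(hot, 0), "> 0")
  expect_error(tcp_fenwick(uniform_ddvh(84.6, scale = "physical"), 4.9),
               "EQD2")
})

test_that("Webb-Nahum reduces to the Poisson closed form when sd is zero", {
  p0 <- webb_nahum_params(alpha_sd = 0)
  u <- uniform_ddvh(80, volume = 5)
  expect_equal(tcp_webb_nahum(u, p0),
               exp(-1e8 * 5 * exp(-0.3 * 80)), tolerance = 1e-12)
  # closed-form D50 inversion at rho V = 1e8
  d50 <- log(1e8 / log(2)) / 0.3
  u50 <- uniform_ddvh(d50, volume = 1)
  expect_equal(tcp_webb_nahum(u50, p0), 0.5, tolerance = 1e-10)
})

test_that("Webb-Nahum quadrature matches the dense trapezoid oracle", {
  set.seed(11)
  p <- webb_nahum_params()
  for (i in 1:5) {
    d <- random_ddvh(n_bins = 20, max_dose = 150, total_volume = 8,
                     scale = "EQD2")
    expect_equal(tcp_webb_nahum(d, p), wn_trapezoid_oracle(d, p),
                 tolerance = 1e-6)
  }
})

test_that("survival EUD anchors, dominates cold spots and resists underflow", {
  expect_equal(cell_kill_eud(uniform_ddvh(51.24), 0.3), 51.24)
  expect_equal(tcp_eud(uniform_ddvh(51.24)), 0.5, tolerance = 1e-12)
  split <- ddvh(c(0, 100), c(5, 5), scale = "EQD2")
  expect_equal(cell_kill_eud(split, 0.3),
               -log(0.5 * (1 + exp(-30))) / 0.3, tolerance = 1e-12)
  # extreme doses must not underflow to Inf/NaN
  expect_true(is.finite(cell_kill_eud(uniform_ddvh(5000), 0.3)))
  expect_equal(tcp_eud(uniform_ddvh(0)), 0)
})

test_that("Nitin TCP anchors at BED10 = c L and respects monotonicity", {
  s <- fraction_scheme(4, 12)
  # logistic center: c L equals the scheme BED10
  expect_equal(
    tcp_nitin(s, tumor_diameter = 10.56, dose_basis = "prescription"), 0.5,
    tolerance = 1e-12
  )
  expect_equal(
    tcp_nitin(s, tumor_diameter = 2.3, dose_basis = "prescription"),
    1 / (1 + exp((23 - 105.6) / 31)), tolerance = 1e-12
  )
  # mean-GTV basis uses the DVH mean dose
  g <- ddvh(c(48, 60), c(5, 5), scale = "physical")
  expect_equal(
    tcp_nitin(s, g, 2.3),
    1 / (1 + exp((23 - 54 * (1 + 54 / 40)) / 31)), tolerance = 1e-12
  )
  expect_lt(tcp_nitin(s, g, 3), tcp_nitin(s, g, 2))
  expect_error(tcp_nitin(s, g, -2), "> 0")
  expect_error(tcp_nitin(s, tumor_diameter = 2.3), "requires gtv_ddvh")
})

test_that("prescription-basis Nitin TCP follows scheme BED10 exactly", {
  b <- vapply(default_schemes(), bed, 0, alpha_beta = 10)
  tcp <- vapply(default_schemes(), tcp_nitin, 0, tumor_diameter = 2.3,
                dose_basis = "prescription")
  expect_equal(order(tcp), order(b))
  expect_equal(unname(tcp["1x30"]), unname(tcp["6x10"]))  # BED10 tie
})

test_that("tcp_all converts once, bounds outputs and is deterministic", {
  set.seed(3)
  g <- random_ddvh(n_bins = 40, max_dose = 1.3, total_volume = 4.9)
  g <- ddvh(g$dose * 48, g$volume, scale = "physical")
  s <- fraction_scheme(4, 12)
  r1 <- tcp_all(g, s, 4.9, 2.3)
  r2 <- tcp_all(g, s, 4.9, 2.3)
  expect_identical(r1, r2)
  expect_true(all(r1$per_model >= 0 & r1$per_model <= 1))
  expect_gte(r1$median_tcp, min(r1$per_model))
  expect_lte(r1$median_tcp, max(r1$per_model))
  expect_named(r1$per_model,
               c("martel", "fenwick", "webb_nahum", "eud", "nitin"))
  # a uniform EQD2-equivalent input hits the Martel anchor exactly
  u <- ddvh(48, 4.9, scale = "physical")
  eq_dose <- eqd2_total(48, 4, 10)
  expect_equal(
    tcp_all(u, s, 4.9, 2.3)$per_model[["martel"]],
    martel_dose_response(eq_dose), tolerance = 1e-12
  )
  expect_error(tcp_all(convert_ddvh(u, s, 10, "EQD2"), s, 4.9, 2.3),
               "physical")
})
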