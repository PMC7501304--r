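test_that("planted couplings follow the class power law with chosen signs", {
  pm <- planted_couplings(max_lag = 3, sign_scheme = "all_positive",
                          A = 0.2, beta = 1)
  expect_equal(pm$J, c(0.2, 0.1, 0.2 / 3), tolerance = 1e-12)

  p1 <- planted_couplings(class_preset("AF"), max_lag = 30,
                          sign_scheme = "random", seed = 4)
  p2 <- planted_couplings(class_preset("AF"), max_lag = 30,
                          sign_scheme = "random", seed = 4)
  expect_identical(p1$J, p2$J)

  # magnitudes strictly decreasing before any rescale, for beta > 0
  mags <- abs(p1$J) / p1$rescale_factor
  expect_true(all(diff(mags) < 0))

  alt <- planted_couplings(max_lag = 4, sign_scheme = "alternating",
                           A = 0.1, beta = 1)
  expect_equal(sign(alt$J), c(1, -1, 1, -1))
})

test_that("stationarity is enforced and long runs have stable variance", {
  pm <- planted_couplings(class_preset("H"), max_lag = 100,
                          sign_scheme = "all_positive")
  expect_lt(pm$spectral_radius, 1)
  expect_lt(pm$rescale_factor, 1)   # all-positive H couplings need rescaling

  z <- sample_autoregressive(pm, 40000, seed = 8)
  v1 <- var(as.numeric(z)[1:20000])
  v2 <- var(as.numeric(z)[20001:40000])
  expect_lt(abs(v1 - v2) / v1, 0.35)  # near-critical: generous stability check

  pm2 <- planted_couplings(max_lag = 10, sign_scheme = "random", seed = 2,
                           A = 0.2, beta = 1, scale_to_radius = 0.9)
  expect_equal(pm2$spectral_radius, 0.9, tolerance = 1e-6)
})

test_that("the AR sampler reproduces closed-form AR(1) autocorrelation", {
  m <- coupling_model(0.5)
  z <- sample_autoregressive(m, 1e5, seed = 6)
  a <- autocorrelation(z, 5)$C
  expect_equal(a[2:6], 0.5^(1:5), tolerance = 0.02)

  zw <- sample_autoregressive(coupling_model(0), 1e4, seed = 6)
  expect_lt(abs(autocorrelation(zw, 1)$C[2]), 3 / sqrt(1e4))

  z2 <- sample_autoregressive(m, 1000, seed = 99)
  z3 <- sample_autoregressive(m, 1000, seed = 99)
  expect_identical(as.numeric(z2), as.numeric(z3))

  expect_error(sample_autoregressive(coupling_model(1.05), 100, seed = 1),
               "non-stationary")
})

test_that("physical wrapping inverts standardization", {
  z <- std_vec <- structure(c(-1, 1), class = "std_series")
  rr <- make_raw_rr(c(-1, 1), 900, 100)
  expect_equal(rr$intervals, c(800, 1000))

  zz <- sample_autoregressive(coupling_model(c(0.3, -0.1)), 1e4, seed = 5)
  rr2 <- make_raw_rr(zz, 820, 40)
  back <- standardize(rr2)
  expect_lt(max(abs(as.numeric(back) - as.numeric(zz))), 1e-9)

  expect_error(make_raw_rr(c(-30, 30), 800, 50), "nonpositive")
})

test_that("shaped noise carries its planted spectrum", {
  for (g in c(0.5, 1.5)) {
    z <- spectral_shaped_noise(g, 2^17, seed = 31)
    gh <- suppressWarnings(fit_psd_power_law(welch_psd(z, 4096)))$gamma
    expect_lt(abs(gh - g), 0.05)
  }
  z1 <- spectral_shaped_noise(1, 2^12, seed = 9)
  z2 <- spectral_shaped_noise(1, 2^12, seed = 9)
  expect_identical(as.numeric(z1), as.numeric(z2))
  expect_error(spectral_shaped_noise(3, 2^12, 1), "\\[0, 2\\]")
  expect_error(spectral_shaped_noise(1, 3000, 1), "power of two")
})
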