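test_that("Welch PSD localizes line spectra and conserves variance", {
  n <- 2^14
  z <- sin(2 * pi * 0.1 * seq_len(n))
  est <- welch_psd(z, segment_length = 1000)   # 0.1 lies on this grid
  expect_equal(est$frequency[which.max(est$power)], 0.1)

  zw <- white_std(2^16, seed = 13)
  est <- welch_psd(zw, segment_length = 4096)
  total <- sum(est$power) / attr(est, "segment_length")
  expect_lt(abs(total - 1), 0.05)     # Parseval, unit variance

  expect_error(welch_psd(zw[1:100], segment_length = 4096), "exceeds")
  expect_error(welch_psd(zw, 4096, overlap = 1), "overlap")
})

test_that("log-log line fits recover exact and planted spectral exponents", {
  f <- seq_len(2048) / 4096
  exact <- structure(data.frame(frequency = f, power = 2 * f^(-1)),
                     class = c("welch_psd", "data.frame"))
  fit <- suppressWarnings(fit_psd_power_law(exact, band = c(1e-3, 0.4)))
  expect_equal(fit$gamma, 1, tolerance = 1e-10)
  expect_equal(fit$alpha, 2, tolerance = 1e-10)

  z0 <- spectral_shaped_noise(0, 2^16, seed = 2)
  g0 <- suppressWarnings(fit_psd_power_law(welch_psd(z0, 4096)))
  expect_lt(abs(g0$gamma), 0.05)

  z1 <- spectral_shaped_noise(1, 2^16, seed = 2)
  g1 <- suppressWarnings(fit_psd_power_law(welch_psd(z1, 4096)))
  expect_lt(abs(g1$gamma - 1), 0.05)

  # iid Gaussian noise: flat up to sampling error
  gw <- suppressWarnings(
    fit_psd_power_law(welch_psd(white_std(2^16, 14), 4096)))
  expect_lt(abs(gw$gamma), 0.15)
})

test_that("the fit band tightens on short series and rejects starvation", {
  z <- spectral_shaped_noise(1, 2^12, seed = 3)
  est <- welch_psd(z, 1024)
  expect_warning(fit_psd_power_law(est, band = c(1e-4, 5e-3)), "widened")
  expect_error(fit_psd_power_law(est, band = c(0.4, 0.5)),
               NA)  # enough bins near Nyquist at this resolution
})

test_that("the exponent is scale-invariant and stable in segment length", {
  z <- spectral_shaped_noise(1, 2^16, seed = 4)
  zn <- as.numeric(z)
  g1 <- suppressWarnings(fit_psd_power_law(welch_psd(zn, 2048)))$gamma
  g2 <- suppressWarnings(fit_psd_power_law(welch_psd(5 * zn, 2048)))$gamma
  expect_equal(g1, g2, tolerance = 1e-12)

  g4 <- suppressWarnings(fit_psd_power_law(welch_psd(zn, 4096)))$gamma
  expect_lt(abs(g4 - g1), 0.05)
})

test_that("exponent scatter pairs experimental and synthetic slopes per patient", {
  m <- coupling_model(c(0.5, -0.2), sigma_J = c(0, 0))
  patients <- lapply(1:2, function(i)
    sample_autoregressive(m, 2^12 + 2, seed = 20 + i))
  sc <- exponent_scatter(m, patients, n_synth = 1, seed = 5,
                         segment_length = 512, band = c(5e-3, 0.2))
  expect_equal(nrow(sc), 2L)
  # sigma_J = 0 and n_synth = 1: the synthetic exponent is deterministic
  sc2 <- exponent_scatter(m, patients, n_synth = 1, seed = 99,
                          segment_length = 512, band = c(5e-3, 0.2))
  expect_equal(sc$gamma_synthetic_mean, sc2$gamma_synthetic_mean)
})
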