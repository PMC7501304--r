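test_that("noiseless power-law magnitudes are recovered to high precision", {
  tau <- 1:100
  m <- coupling_model(0.3 * tau^(-1.2) * rep_len(c(1, -1), 100))
  fit <- fit_power_law_tail(m)
  expect_equal(fit$A, 0.3, tolerance = 1e-8)
  expect_equal(fit$beta, 1.2, tolerance = 1e-8)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)

  flat <- coupling_model(rep(0.2, 60))
  ff <- fit_power_law_tail(flat)
  expect_lt(abs(ff$beta), 1e-8)
  expect_equal(ff$A, 0.2, tolerance = 1e-8)
})

test_that("normalized residuals vanish on exact data and rescale correctly", {
  tau <- 1:80
  J <- 0.25 * tau^(-1.0)
  m <- coupling_model(J, sigma_J = rep(0.01, 80))
  fit <- fit_power_law_tail(m)
  r <- normalized_residuals(fit, m)
  expect_lt(max(abs(r)), 1e-6)

  # joint rescaling of |J| and sigma_J leaves normalized residuals alone
  m2 <- coupling_model(J * 3, sigma_J = rep(0.03, 80))
  fit2 <- fit_power_law_tail(m2)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-8)
  expect_equal(fit2$A, 3 * fit$A, tolerance = 1e-8)
  expect_equal(normalized_residuals(fit2, m2), r, tolerance = 1e-6)

  m0 <- coupling_model(J)   # sigma all zero -> uniform weights
  expect_error(normalized_residuals(fit_power_law_tail(m0), m0),
               "sigma_J is zero")
})

test_that("the selected range maximizes adjusted R-squared deterministically", {
  set.seed(31)
  tau <- 1:60
  y <- 0.3 * tau^(-1.1) * exp(rnorm(60, sd = 0.2))
  m <- coupling_model(y, sigma_J = 0.2 * 0.3 * tau^(-1.1))
  f1 <- fit_power_law_tail(m, tau_lo_max = 20)
  f2 <- fit_power_law_tail(m, tau_lo_max = 20)
  expect_identical(f1$beta, f2$beta)
  expect_true(all(f1$adj_r2 >= f1$candidates$adj_r2 - 1e-12))
  expect_equal(f1$candidates$tau_lo, 1:20)
})

test_that("zero couplings are excluded and tiny sigmas rejected", {
  tau <- 1:40
  J <- 0.3 * tau^(-1.0)
  J[c(5, 9)] <- 0
  m <- coupling_model(J, sigma_J = rep(0.01, 40))
  fit <- fit_power_law_tail(m, tau_lo_max = 3)
  expect_equal(fit$n_excluded, 2L)
  expect_false(any(fit$tau %in% c(5, 9)))

  bad <- coupling_model(J, sigma_J = rep(1e-9, 40))
  expect_error(fit_power_law_tail(bad), "1e-8")

  few <- coupling_model(c(0.3, 0, 0, 0.1, 0))
  expect_error(fit_power_law_tail(few, tau_lo_max = 4), "4 usable points")
})

test_that("the weighted estimator is nearly unbiased under multiplicative noise", {
  set.seed(77)
  tau <- 1:50
  mu <- 0.3 * tau^(-1.0)
  betas <- replicate(200, {
    y <- abs(mu * (1 + 0.05 * rnorm(50)))
    m <- coupling_model(y, sigma_J = 0.05 * mu)
    fit_power_law_tail(m, tau_lo_max = 2)$beta
  })
  expect_lt(abs(mean(betas) - 1.0), 0.02)
})
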