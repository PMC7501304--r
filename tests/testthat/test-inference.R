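test_that("AdaGrad steps follow the accumulator arithmetic exactly", {
  st <- list(acc = c(0, 0), learn_rate = 0.05, epsilon = 1e-8)
  p <- c(J1 = 0, h = 0)

  up <- adagrad_step(p, c(0.4, -0.2), st)
  expect_equal(unname(up$params),
               0.05 * c(0.4, -0.2) / (c(0.4, 0.2) + 1e-8),
               tolerance = 1e-12)        # first step magnitude ~ lr
  expect_equal(up$state$acc, c(0.16, 0.04))

  up0 <- adagrad_step(p, c(0, 0), st)
  expect_identical(unname(up0$params), c(0, 0))
  expect_identical(up0$state$acc, c(0, 0))

  # two identical gradients, hand-rolled
  g <- c(0.4, -0.2)
  up1 <- adagrad_step(p, g, st)
  up2 <- adagrad_step(up1$params, g, up1$state)
  acc2 <- 2 * g^2
  expect_equal(unname(up2$params),
               unname(up1$params) + 0.05 * g / (sqrt(acc2) + 1e-8),
               tolerance = 1e-14)

  expect_error(adagrad_step(p, c(NaN, 0), st), "J1")
})

test_that("a planted noiseless recursion is recovered exactly", {
  z <- period4_series(400)       # satisfies z_t = -z_{t-2}
  fit <- fit_batch(z, max_lag = 2, lambda = 0,
                   control = adagrad_control(max_epochs = 5000))
  expect_lt(max(abs(fit$J - c(0, -1))), 1e-4)
  expect_lt(abs(fit$h), 1e-4)
})

test_that("white noise yields near-zero couplings", {
  z <- white_std(1e4, seed = 9)
  fit <- suppressWarnings(fit_batch(z, max_lag = 10, lambda = 1e-2))
  expect_lt(max(abs(fit$J)), 3 / sqrt(1e4))
})

test_that("the objective is nondecreasing along the ascent path", {
  z <- sample_autoregressive(coupling_model(c(0.4, -0.15, 0.1)),
                             n = 2000, seed = 3)
  objs <- vapply(c(5, 20, 100, 400), function(k) {
    f <- suppressWarnings(
      fit_batch(z, max_lag = 5, lambda = 1e-2,
                control = adagrad_control(max_epochs = k)))
    regularized_objective(z, f, 1e-2)
  }, numeric(1))
  expect_true(all(diff(objs) >= -1e-10))
})

test_that("identical batches give exactly zero spread", {
  z <- white_std(500, 21)
  fit <- maxent_pairwise(list(z), max_lag = 5, lambda = 1e-2,
                         resample = resample_plan(2, 1), seed = 1)
  expect_identical(fit$sigma_J, rep(0, 5))
  expect_identical(fit$sigma_h, 0)
})

test_that("resampled inference is reproducible and well-formed", {
  series <- lapply(1:6, function(i) white_std(600, 30 + i))
  f1 <- maxent_pairwise(series, max_lag = 8, lambda = 1e-2,
                        resample = resample_plan(10, 3), seed = 77)
  f2 <- maxent_pairwise(series, max_lag = 8, lambda = 1e-2,
                        resample = resample_plan(10, 3), seed = 77)
  expect_identical(f1$J, f2$J)
  expect_identical(f1$sigma_J, f2$sigma_J)
  expect_true(all(f1$sigma_J >= 0 & is.finite(f1$sigma_J)))
  expect_error(maxent_pairwise(series, max_lag = 8,
                               resample = resample_plan(10, 7), seed = 1),
               "batch_size")
})

test_that("stronger regularization never increases the penalized norm", {
  z <- sample_autoregressive(coupling_model(c(0.4, -0.15, 0.1)),
                             n = 3000, seed = 3)
  pen <- vapply(c(0, 0.01, 0.1, 1, 10), function(l) {
    f <- suppressWarnings(fit_batch(z, max_lag = 5, lambda = l))
    sum(temporal_penalty(1:5) * f$J^2)
  }, numeric(1))
  expect_true(all(diff(pen) <= 1e-10))
})

test_that("couplings planted in a shared model are recovered within 2 sigma", {
  truth <- planted_couplings(class_preset("AF"), max_lag = 20,
                             sign_scheme = "random", seed = 5)
  series <- lapply(1:10, function(i)
    sample_autoregressive(truth, 4000, seed = 100 + i))
  fit <- suppressWarnings(
    maxent_pairwise(series, max_lag = 20, lambda = 1e-3,
                    resample = resample_plan(20, 4), seed = 9))
  z <- abs(fit$J - truth$J) / fit$sigma_J
  # allow a small fraction of outliers; sigma_J is a batch spread
  expect_lt(mean(z > 2), 0.25)
  expect_lt(sqrt(mean((fit$J - truth$J)^2)), 0.05)
})
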