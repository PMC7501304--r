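test_that("conditional log-density is a unit-variance Gaussian around the convolution mean", {
  m0 <- coupling_model(rep(0, 3), h = 0)
  expect_equal(conditional_log_density(0, c(0, 0, 0), m0),
               -0.5 * log(2 * pi), tolerance = 1e-9)

  m1 <- coupling_model(0.5, h = 0.2)
  expect_equal(conditional_log_density(0.7, 1.0, m1), -0.5 * log(2 * pi),
               tolerance = 1e-12)   # residual exactly zero

  expect_error(conditional_log_density(0, c(1, 2), m1), "window length")

  # normalization by quadrature for random parameters
  set.seed(5)
  for (rep in 1:5) {
    m <- coupling_model(rnorm(4) * 0.3, h = rnorm(1) * 0.2)
    w <- rnorm(4)
    total <- stats::integrate(function(x) vapply(x, function(xi)
      exp(conditional_log_density(xi, w, m)), numeric(1)),
      lower = -10, upper = 10, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("pseudo-log-likelihood is the nonpositive sliding-window average", {
  fib <- fibonacci_series(12)
  mfib <- coupling_model(c(1, 1), h = 0)
  expect_equal(pseudo_log_likelihood(fib, mfib), 0)

  # single-window case equals the direct one-term evaluation
  z4 <- c(0.3, -0.2, 0.5, 0.1)
  m3 <- coupling_model(c(0.2, -0.1, 0.4), h = 0.05)
  direct <- -0.5 * (z4[4] - 0.05 -
                      (0.2 * z4[3] - 0.1 * z4[2] + 0.4 * z4[1]))^2
  expect_equal(pseudo_log_likelihood(z4, m3), direct, tolerance = 1e-14)

  # brute-force loop oracle
  set.seed(8)
  z <- rnorm(50)
  m <- coupling_model(c(0.3, -0.2, 0.1), h = 0.02)
  acc <- 0
  for (L in 3:49) {
    pred <- m$h + sum(m$J * z[L:(L - 2)])
    acc <- acc - 0.5 * (z[L + 1] - pred)^2
  }
  expect_equal(pseudo_log_likelihood(z, m), acc / 47, tolerance = 1e-12)

  expect_lte(pseudo_log_likelihood(z, m), 0)
  expect_error(pseudo_log_likelihood(z[1:3], m), "must exceed")
})

test_that("regularized objective applies the log-squared lag penalty", {
  fib <- fibonacci_series(12)
  mfib <- coupling_model(c(1, 1), h = 0)
  expect_equal(regularized_objective(fib, mfib, 0),
               pseudo_log_likelihood(fib, mfib))
  expect_equal(regularized_objective(fib, mfib, 2),
               -(log(2)^2 + log(3)^2), tolerance = 1e-12)

  z <- white_std(100, 2)
  m <- coupling_model(c(0.2, 0.1), h = 0.1)
  objs <- vapply(c(0, 0.1, 1, 5), function(l)
    regularized_objective(z, m, l), numeric(1))
  expect_true(all(diff(objs) <= 0))
  expect_error(regularized_objective(z, m, -1), "nonnegative")
})

test_that("analytic gradient matches finite differences and hand computation", {
  z <- white_std(200, 3)
  m <- coupling_model(rnorm(10, sd = 0.1), h = 0.03)
  lam <- 0.3
  g <- objective_gradient(z, m, lam)
  eps <- 1e-6
  for (k in c(1, 4, 10)) {
    mp <- m; mm <- m
    mp$J[k] <- mp$J[k] + eps; mm$J[k] <- mm$J[k] - eps
    num <- (regularized_objective(z, mp, lam) -
              regularized_objective(z, mm, lam)) / (2 * eps)
    expect_equal(g$grad_J[k], num, tolerance = 1e-6)
  }
  mp <- m; mm <- m
  mp$h <- mp$h + eps; mm$h <- mm$h - eps
  num_h <- (regularized_objective(z, mp, lam) -
              regularized_objective(z, mm, lam)) / (2 * eps)
  expect_equal(g$grad_h, num_h, tolerance = 1e-6)

  # zero-residual stationary point at lambda = 0
  fib <- fibonacci_series(12)
  g0 <- objective_gradient(fib, coupling_model(c(1, 1), h = 0), 0)
  expect_equal(g0$grad_J, c(0, 0))
  expect_equal(g0$grad_h, 0)

  # 4-point toy, T = 1, by hand
  z4 <- c(1, 2, -1, 0.5); j <- 0.3; h <- 0.1; lam <- 0.2
  delta <- (z4[2:4] - h - j * z4[1:3]) / 3
  gt <- objective_gradient(z4, coupling_model(j, h), lam)
  expect_equal(gt$delta, delta, tolerance = 1e-14)
  expect_equal(gt$grad_J, sum(delta * z4[1:3]) - lam * log(2)^2 * j,
               tolerance = 1e-14)
  expect_equal(gt$grad_h, sum(delta) - lam * h, tolerance = 1e-14)
})

test_that("adding a constant shifts the bias gradient exactly", {
  z <- as.numeric(white_std(120, 6))
  J <- c(0.25, -0.15, 0.05)
  cshift <- 0.7
  m0 <- coupling_model(J, h = 0.1)
  m1 <- coupling_model(J, h = 0.1 + cshift * (1 - sum(J)))
  g0 <- objective_gradient(z, m0, 0)
  g1 <- objective_gradient(z + cshift, m1, 0)
  expect_equal(g1$grad_h, g0$grad_h, tolerance = 1e-12)
  # residuals are identical, so J-gradients differ only through the
  # shifted regressors: Delta_L * c sums to c * sum(Delta)
  expect_equal(g1$grad_J - g0$grad_J,
               rep(cshift * sum(g0$delta), 3), tolerance = 1e-12)
})

test_that("second-moment multiplier identity holds and samples confirm it", {
  expect_identical(lambda2_from_second_moment(1), -0.5)
  expect_identical(lambda2_from_second_moment(0.5), -1)
  expect_error(lambda2_from_second_moment(0), "positive")

  # prior-only model with lambda2 = -1/(2 mu2) is N(0, mu2)
  mu2 <- 1.7
  l2 <- lambda2_from_second_moment(mu2)
  set.seed(10)
  draws <- rnorm(1e6, sd = sqrt(-1 / (2 * l2)))
  se <- sqrt(2) * mu2 / sqrt(1e6)
  expect_lt(abs(mean(draws^2) - mu2), 3 * se)
})

test_that("kernel determinant equals lambda2^N for any couplings", {
  r <- kernel_determinant_check(-0.5, c(0.3, -0.2, 0.1, 0.4), 5)
  expect_equal(r$numeric, -0.03125, tolerance = 1e-12)
  expect_equal(r$analytic, -0.03125)

  r1 <- kernel_determinant_check(-0.5, 0.7, 1)
  expect_equal(r1$numeric, -0.5)

  set.seed(12)
  for (n in c(3, 8)) {
    lt <- rnorm(n - 1)
    r <- kernel_determinant_check(-0.5, lt, n)
    expect_equal(r$numeric, r$analytic, tolerance = 1e-10)
  }
  expect_error(kernel_determinant_check(-0.5, 1, 13), "n <= 12")
})
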