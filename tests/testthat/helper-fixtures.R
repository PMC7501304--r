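# Shared fixtures, all generated in code.

# short standardized white-noise series
white_std <- function(n, seed) {
  set.seed(seed)
  standardize(rnorm(n))
}

# a series satisfying z_t = z_{t-1} + z_{t-2} exactly (zero residuals
# for J = (1, 1), h = 0)
fibonacci_series <- function(n = 12) {
  z <- c(1, 1)
  for (k in 3:n) z[k] <- z[k - 1] + z[k - 2]
  z
}

# period-4 sequence satisfying z_t = -z_{t-2} exactly (J = (0, -1))
period4_series <- function(n = 400) {
  rep(c(1, 2, -1, -2), length.out = n)
}

# brute-force autocorrelation via an explicit double loop
acf_brute <- function(z, lag_max) {
  z <- as.numeric(z)
  n <- length(z)
  vapply(0:lag_max, function(tau) {
    s <- 0
    for (k in 1:(n - tau)) s <- s + z[k] * z[k + tau]
    s / (n - tau)
  }, numeric(1))
}
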