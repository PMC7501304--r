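#' Bare coupling model
#'
#' Constructs a pairwise maximum-entropy coupling model without fitting:
#' delayed couplings `J` (tau = 1..T), bias `h`, and optional
#' uncertainties. Fitted models from [maxent_pairwise()] inherit from
#' this class; the constructor is useful for planting ground truths and
#' for the generation utilities.
#'
#' @param J numeric vector of couplings, `J[tau]` for tau = 1..T.
#' @param h bias (scalar).
#' @param sigma_J nonnegative uncertainties, same length as `J`.
#' @param sigma_h nonnegative uncertainty of `h`.
#' @param class_label clinical class the model refers to.
#' @return object of class `"coupling_model"`.
#' @export
coupling_model <- function(J, h = 0, sigma_J = rep(0, length(J)),
                           sigma_h = 0, class_label = "UNKNOWN") {
  J <- as.numeric(J); sigma_J <- as.numeric(sigma_J)
  if (length(sigma_J) != length(J))
    stop("sigma_J must match J in length")
  if (any(sigma_J < 0) || sigma_h < 0)
    stop("uncertainties must be nonnegative")
  structure(list(J = J, h = as.numeric(h)[1L], sigma_J = sigma_J,
                 sigma_h = as.numeric(sigma_h)[1L],
                 max_lag = length(J), class_label = class_label),
            class = "coupling_model")
}

#' @export
print.coupling_model <- function(x, ...) {
  cat(sprintf("pairwise coupling model [%s]: T = %d, h = %.4g\n",
              x$class_label, x$max_lag, x$h))
  k <- min(5L, x$max_lag)
  cat("  J(1..", k, "): ", paste(sprintf("%.4g", x$J[1:k]), collapse = ", "),
      if (x$max_lag > k) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Temporal regularizer weight
#'
#' The lag-dependent ridge weight `f(tau) = log(1 + tau)^2` applied to
#' each coupling, mild at small lags and growing slowly, so that genuine
#' short-range structure is retained while spurious long-lag couplings
#' are discouraged.
#'
#' @param tau integer lag(s).
#' @return numeric vector of weights.
#' @export
temporal_penalty <- function(tau) log(1 + tau)^2

#' Conditional log-density of the next beat
#'
#' The pairwise maximum-entropy model with a standard-normal prior has a
#' closed-form one-step conditional: given the last `T` standardized
#' values, the next value is Gaussian with unit variance and mean
#' `h + sum_tau J(tau) z[t - tau]`. This returns its log-density,
#' constant `-log(2*pi)/2` included (so the density integrates to 1).
#'
#' @param z_next candidate next value.
#' @param window numeric vector of length `T`, ordered oldest to newest:
#'   `window[T]` is the most recent observation (lag 1).
#' @param model a [coupling_model()].
#' @return log-density (scalar).
#' @export
conditional_log_density <- function(z_next, window, model) {
  T_ <- model$max_lag
  if (length(window) != T_)
    stop("window length ", length(window), " != model order ", T_)
  if (!all(is.finite(window)) || !is.finite(z_next))
    stop("window and z_next must be finite")
  mu <- model$h + sum(model$J * window[T_:1])  # window[T+1-tau] = lag tau
  -0.5 * log(2 * pi) - 0.5 * (z_next - mu)^2
}

# One-step prediction residuals z[t] - h - sum_tau J[tau] z[t-tau],
# for t = (T+1)..N; vectorized via a one-sided convolution filter.
one_step_residuals <- function(z, J, h) {
  zv <- as.numeric(z)
  n <- length(zv)
  T_ <- length(J)
  if (n <= T_) stop("series length (", n, ") must exceed model order (", T_, ")")
  pred <- stats::filter(zv, c(0, J), method = "convolution", sides = 1)
  zv[(T_ + 1L):n] - h - pred[(T_ + 1L):n]
}

#' Sliding-window pseudo-log-likelihood
#'
#' The per-series objective to be maximized:
#' \deqn{-\frac{1}{2(N-T)} \sum_{L=T}^{N-1}\Big(z_{L+1} - h -
#'   \sum_{\tau=1}^{T} J(\tau) z_{L+1-\tau}\Big)^2,}
#' the average one-step conditional log-probability over every window
#' position, with the Gaussian constant dropped. Always nonpositive;
#' zero exactly when the series satisfies the model recursion.
#'
#' @param z a `"std_series"` or numeric vector of length `> T`.
#' @param model a [coupling_model()].
#' @return scalar pseudo-log-likelihood.
#' @export
pseudo_log_likelihood <- function(z, model) {
  r <- one_step_residuals(z, model$J, model$h)
  -sum(r^2) / (2 * length(r))
}

#' Regularized pseudo-likelihood objective
#'
#' [pseudo_log_likelihood()] minus the ridge penalties
#' `lambda/2 * h^2` and `lambda/2 * sum_tau f(tau) J(tau)^2` with
#' `f = ` [temporal_penalty()].
#'
#' @inheritParams pseudo_log_likelihood
#' @param lambda nonnegative regularization weight.
#' @return scalar objective (to be maximized).
#' @export
regularized_objective <- function(z, model, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  pseudo_log_likelihood(z, model) -
    (lambda / 2) * model$h^2 -
    (lambda / 2) * sum(temporal_penalty(seq_along(model$J)) * model$J^2)
}

#' Ascent gradient of the regularized objective
#'
#' Exact gradient of [regularized_objective()] with respect to
#' `(J, h)`, in the per-window residual form: with
#' `Delta_L = (z_{L+1} - h - sum_tau J(tau) z_{L+1-tau}) / (N-T)`,
#' `grad_J(tau) = sum_L Delta_L z_{L+1-tau} - lambda f(tau) J(tau)` and
#' `grad_h = sum_L Delta_L - lambda h`.
#'
#' @inheritParams regularized_objective
#' @return list with `grad_J` (length `T`), `grad_h`, and the residual
#'   vector `delta` (`Delta_L`, one per window position).
#' @export
objective_gradient <- function(z, model, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  zv <- as.numeric(z)
  T_ <- model$max_lag
  r <- one_step_residuals(zv, model$J, model$h)
  nw <- length(r)                       # N - T windows
  delta <- r / nw
  # sum_L Delta_L z_{L+1-tau}: cross-correlation of delta with the lagged series
  grad_J <- vapply(seq_len(T_), function(tau)
    sum(delta * zv[(T_ + 1L - tau):(length(zv) - tau)]), numeric(1))
  grad_J <- grad_J - lambda * temporal_penalty(seq_len(T_)) * model$J
  grad_h <- sum(delta) - lambda * model$h
  if (!all(is.finite(grad_J)) || !is.finite(grad_h))
    stop("non-finite gradient encountered")
  list(grad_J = grad_J, grad_h = grad_h, delta = delta)
}

#' Second-moment Lagrange multiplier
#'
#' With vanishing couplings and bias, the maximum-entropy stationarity
#' condition ties the multiplier on the second moment to the moment
#' itself: `mu2 = -1/(2*lambda2)`. This inverts that relation; for a
#' standardized series (`mu2 = 1`) it returns exactly `-1/2`.
#'
#' @param mu2 positive second moment.
#' @return `lambda2 = -1/(2*mu2)`.
#' @export
lambda2_from_second_moment <- function(mu2) {
  if (!is.finite(mu2) || mu2 <= 0) stop("mu2 must be a positive number")
  -1 / (2 * mu2)
}

#' Kernel determinant identity check
#'
#' The quadratic form of the finite-N model has kernel
#' `lambda2 * I + L`, where `L` is the strictly upper-triangular Toeplitz
#' matrix `L[n, m] = lambda_{m-n}` for `m > n`. Being triangular, its
#' determinant is `lambda2^N` regardless of the couplings. This builds
#' the matrix explicitly (small `N` only) and returns the numeric
#' determinant next to the analytic value.
#'
#' @param lambda2 diagonal value.
#' @param lambda_tau coupling vector (recycled/truncated to `N - 1`).
#' @param n matrix size, at most 12.
#' @return list with `numeric` (dense determinant) and `analytic`
#'   (`lambda2^n`).
#' @export
kernel_determinant_check <- function(lambda2, lambda_tau, n) {
  if (n > 12L) stop("explicit construction limited to n <= 12")
  lt <- rep_len(as.numeric(lambda_tau), max(1L, n - 1L))
  K <- diag(lambda2, n)
  if (n > 1L)
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        K[i, j] <- K[i, j] + lt[j - i]
  list(numeric = det(K), analytic = lambda2^n)
}
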