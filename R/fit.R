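#' AdaGrad optimizer settings
#'
#' @param learn_rate base learning rate.
#' @param epsilon numerical floor added to the root accumulator.
#' @param max_epochs maximum number of ascent epochs per fit.
#' @param tol stop when the gradient infinity-norm falls below this.
#' @return list of class `"adagrad_control"`.
#' @export
adagrad_control <- function(learn_rate = 0.05, epsilon = 1e-8,
                            max_epochs = 500L, tol = 1e-6) {
  stopifnot(learn_rate > 0, epsilon > 0, max_epochs >= 1, tol >= 0)
  structure(list(learn_rate = learn_rate, epsilon = epsilon,
                 max_epochs = as.integer(max_epochs), tol = tol),
            class = "adagrad_control")
}

#' Minibatch resampling plan
#'
#' Uncertainties on the couplings come from refitting the model on many
#' random patient subsets and taking across-subset means and standard
#' deviations. Full-scale analyses use 500 batches of 20 patients;
#' smaller studies scale both down.
#'
#' @param n_batches number of independent refits (M).
#' @param batch_size patients per refit (n), sampled without replacement
#'   within a batch, independently across batches.
#' @return list of class `"resample_plan"`.
#' @export
resample_plan <- function(n_batches = 50L, batch_size = 8L) {
  stopifnot(n_batches >= 2, batch_size >= 1)
  structure(list(n_batches = as.integer(n_batches),
                 batch_size = as.integer(batch_size)),
            class = "resample_plan")
}

#' One AdaGrad ascent step
#'
#' Per-parameter adaptive update: the squared-gradient accumulator grows
#' by `g^2` and the parameter moves by `lr * g / (sqrt(acc) + eps)`
#' (ascent). Exposed mainly for testing; [maxent_pairwise()] drives the
#' full loop.
#'
#' @param params named numeric vector of current parameters.
#' @param grad gradient of the objective at `params` (same length).
#' @param state list with `acc` (accumulator vector), `learn_rate`,
#'   `epsilon`; as created internally or by hand.
#' @return list with updated `params` and `state`.
#' @export
adagrad_step <- function(params, grad, state) {
  if (length(grad) != length(params))
    stop("gradient and parameter vectors differ in length")
  if (!all(is.finite(grad))) {
    bad <- which(!is.finite(grad))[1L]
    nm <- names(params)[bad] %||% as.character(bad)
    stop("non-finite gradient for parameter ", nm)
  }
  state$acc <- state$acc + grad^2
  params <- params + state$learn_rate * grad / (sqrt(state$acc) + state$epsilon)
  list(params = params, state = state)
}

# Per-series sufficient statistics of the sliding-window least-squares
# problem: crossproducts of (z_t, z_{t-1}, ..., z_{t-T}) over all window
# positions, each normalized by the number of windows. The gradient and
# objective built from these are algebraically identical to the
# per-window forms in objective_gradient().
series_stats <- function(z, max_lag) {
  zv <- as.numeric(z)
  n <- length(zv)
  if (n <= max_lag)
    stop("series length (", n, ") must exceed the model order (", max_lag, ")")
  X <- stats::embed(zv, max_lag + 1L)   # columns: z_t, lag1, ..., lagT
  nw <- nrow(X)
  list(C = crossprod(X) / nw, s = colSums(X) / nw, nw = nw)
}

avg_stats <- function(stats_list) {
  k <- length(stats_list)
  C <- stats_list[[1L]]$C
  s <- stats_list[[1L]]$s
  if (k > 1L) for (i in 2:k) {
    C <- C + stats_list[[i]]$C
    s <- s + stats_list[[i]]$s
  }
  list(C = C / k, s = s / k)
}

# Gradient and objective value from averaged sufficient statistics.
stats_gradient <- function(theta, st, lambda, f_tau) {
  T_ <- length(theta) - 1L
  J <- theta[seq_len(T_)]; h <- theta[T_ + 1L]
  b <- st$C[-1L, 1L]; A <- st$C[-1L, -1L, drop = FALSE]
  sy <- st$s[1L]; sl <- st$s[-1L]
  AJ <- drop(A %*% J)
  g_J <- b - AJ - h * sl - lambda * f_tau * J
  g_h <- sy - sum(sl * J) - h - lambda * h
  obj <- -0.5 * (st$C[1L, 1L] - 2 * sum(b * J) - 2 * h * sy +
                   sum(J * AJ) + 2 * h * sum(sl * J) + h^2) -
    (lambda / 2) * h^2 - (lambda / 2) * sum(f_tau * J^2)
  list(grad = c(g_J, g_h), obj = obj)
}

# AdaGrad ascent from J = 0, h = 0 on averaged sufficient statistics.
fit_from_stats <- function(st, max_lag, lambda, control) {
  f_tau <- temporal_penalty(seq_len(max_lag))
  theta <- numeric(max_lag + 1L)
  names(theta) <- c(paste0("J", seq_len(max_lag)), "h")
  state <- list(acc = numeric(max_lag + 1L),
                learn_rate = control$learn_rate, epsilon = control$epsilon)
  best <- theta; best_obj <- -Inf
  converged <- FALSE; epochs <- 0L
  objective <- -Inf
  for (e in seq_len(control$max_epochs)) {
    epochs <- e
    ge <- stats_gradient(theta, st, lambda, f_tau)
    objective <- ge$obj
    if (ge$obj > best_obj) { best_obj <- ge$obj; best <- theta }
    if (max(abs(ge$grad)) < control$tol) { converged <- TRUE; break }
    up <- adagrad_step(theta, ge$grad, state)
    theta <- up$params; state <- up$state
  }
  if (!converged) theta <- best
  list(J = unname(theta[seq_len(max_lag)]), h = unname(theta[max_lag + 1L]),
       converged = converged, epochs = epochs,
       objective = if (converged) objective else best_obj)
}

as_series_list <- function(series) {
  if (is.numeric(series)) series <- list(series)
  if (inherits(series, "std_series")) series <- list(series)
  if (!is.list(series) || length(series) == 0L)
    stop("series must be a nonempty list of standardized series")
  series
}

#' Fit one batch of series
#'
#' Point estimate of the coupling model by AdaGrad ascent on the
#' batch-averaged regularized pseudo-likelihood, starting from
#' `J = 0, h = 0`. Returns a [coupling_model()] with zero uncertainties;
#' [maxent_pairwise()] wraps this with minibatch resampling.
#'
#' @param series list of standardized series (each longer than `max_lag`).
#' @param max_lag coupling cutoff T.
#' @param lambda nonnegative regularization weight.
#' @param control an [adagrad_control()].
#' @return a [coupling_model()]; attribute `convergence` records epochs
#'   used and whether the gradient tolerance was met.
#' @export
fit_batch <- function(series, max_lag = 100L, lambda = 1e-2,
                      control = adagrad_control()) {
  series <- as_series_list(series)
  st <- avg_stats(lapply(series, series_stats, max_lag = max_lag))
  fit <- fit_from_stats(st, max_lag, lambda, control)
  if (!fit$converged)
    warning("AdaGrad did not reach gradient tolerance in ", fit$epochs,
            " epochs; returning best iterate", call. = FALSE)
  out <- coupling_model(fit$J, fit$h)
  attr(out, "convergence") <- fit[c("converged", "epochs", "objective")]
  out
}

#' Fit the maximum-entropy pairwise model
#'
#' The main fitting function. Maximizes the regularized Gaussian
#' pseudo-likelihood of a set of standardized RR series by AdaGrad
#' ascent, estimating delayed couplings `J(tau)`, tau = 1..`max_lag`,
#' and a bias `h` (expected near zero for standardized input). With a
#' [resample_plan()], the fit is repeated on `n_batches` random patient
#' subsets of size `batch_size`; reported couplings are across-batch
#' means and the uncertainties `sigma_J`, `sigma_h` the across-batch
#' standard deviations.
#'
#' @param series a list of `"std_series"` (or numeric vectors), one per
#'   patient, or a single series.
#' @param max_lag coupling cutoff T (delayed interactions beyond T are
#'   truncated).
#' @param lambda regularization weight for the ridge penalties on `h`
#'   and `J` (the latter weighted by [temporal_penalty()]).
#' @param resample a [resample_plan()], or `NULL` for a single fit on
#'   all series (uncertainties zero).
#' @param control an [adagrad_control()].
#' @param seed integer seed making batch membership (and hence the fit)
#'   reproducible; required when `resample` is given.
#' @param class_label optional label stored on the model; defaults to
#'   the common label of the input series.
#' @return An object of class `c("maxent_pairwise", "coupling_model")`
#'   with elements `J`, `h`, `sigma_J`, `sigma_h`, `max_lag`,
#'   `class_label`, `lambda`, `control`, `resample`, `batch_J` (matrix
#'   of per-batch couplings, or NULL), `batch_h`, `n_series`,
#'   `n_not_converged`, `seed`.
#' @examples
#' set.seed(1)
#' z <- sample_autoregressive(coupling_model(c(0.5, -0.2)), n = 2000, seed = 1)
#' fit <- maxent_pairwise(z, max_lag = 5, lambda = 0)
#' round(coef(fit), 2)
#' @export
maxent_pairwise <- function(series, max_lag = 100L, lambda = 1e-2,
                            resample = NULL, control = adagrad_control(),
                            seed = NULL, class_label = NULL) {
  series <- as_series_list(series)
  if (is.null(class_label)) {
    labs <- unique(vapply(series, function(z)
      attr(z, "class_label") %||% "UNKNOWN", character(1)))
    class_label <- if (length(labs) == 1L) labs else "MIXED"
  }
  stats_list <- lapply(series, series_stats, max_lag = max_lag)
  n_series <- length(stats_list)

  if (is.null(resample)) {
    fit <- fit_from_stats(avg_stats(stats_list), max_lag, lambda, control)
    J <- fit$J; h <- fit$h
    sigma_J <- rep(0, max_lag); sigma_h <- 0
    batch_J <- NULL; batch_h <- NULL
    n_not_conv <- as.integer(!fit$converged)
  } else {
    stopifnot(inherits(resample, "resample_plan"))
    if (n_series < resample$batch_size)
      stop("need at least batch_size (", resample$batch_size,
           ") series, got ", n_series)
    if (is.null(seed))
      stop("a seed is required for reproducible resampled inference")
    members <- local_seed(seed, {
      lapply(seq_len(resample$n_batches), function(b)
        sample.int(n_series, resample$batch_size, replace = FALSE))
    })
    batch_fits <- lapply(members, function(idx)
      fit_from_stats(avg_stats(stats_list[idx]), max_lag, lambda, control))
    batch_J <- vapply(batch_fits, `[[`, numeric(max_lag), "J")
    batch_J <- matrix(batch_J, nrow = max_lag)    # T x M
    batch_h <- vapply(batch_fits, `[[`, numeric(1), "h")
    J <- rowMeans(batch_J)
    h <- mean(batch_h)
    sigma_J <- apply(batch_J, 1L, stats::sd)
    sigma_h <- stats::sd(batch_h)
    n_not_conv <- sum(!vapply(batch_fits, `[[`, logical(1), "converged"))
  }
  if (n_not_conv > 0L)
    warning(n_not_conv, " fit(s) stopped at max_epochs before reaching ",
            "gradient tolerance; best iterates used", call. = FALSE)

  structure(
    list(J = J, h = h, sigma_J = sigma_J, sigma_h = sigma_h,
         max_lag = as.integer(max_lag), class_label = class_label,
         lambda = lambda, control = control, resample = resample,
         batch_J = batch_J, batch_h = batch_h, n_series = n_series,
         n_not_converged = n_not_conv, seed = seed),
    class = c("maxent_pairwise", "coupling_model"))
}

#' @export
print.maxent_pairwise <- function(x, ...) {
  cat(sprintf("maximum-entropy pairwise model [%s]\n", x$class_label))
  cat(sprintf("  %d series, T = %d, lambda = %.3g\n",
              x$n_series, x$max_lag, x$lambda))
  if (!is.null(x$resample))
    cat(sprintf("  resampled: %d batches of %d\n",
                x$resample$n_batches, x$resample$batch_size))
  cat(sprintf("  h = %.4g (sigma %.2g)\n", x$h, x$sigma_h))
  k <- min(5L, x$max_lag)
  cat("  J(1..", k, "): ",
      paste(sprintf("%.4g", x$J[1:k]), collapse = ", "),
      if (x$max_lag > k) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.maxent_pairwise <- function(object, ...) {
  out <- list(
    class_label = object$class_label,
    n_series = object$n_series,
    max_lag = object$max_lag,
    lambda = object$lambda,
    h = object$h, sigma_h = object$sigma_h,
    n_not_converged = object$n_not_converged,
    couplings = data.frame(tau = seq_len(object$max_lag),
                           J = object$J, sigma_J = object$sigma_J))
  class(out) <- "summary.maxent_pairwise"
  out
}

#' @export
print.summary.maxent_pairwise <- function(x, ...) {
  cat(sprintf("maximum-entropy pairwise model [%s]: %d series, T = %d\n",
              x$class_label, x$n_series, x$max_lag))
  cat(sprintf("  bias h = %.4g +/- %.2g (expected ~0 after standardization)\n",
              x$h, x$sigma_h))
  sig <- abs(x$couplings$J) > 2 * x$couplings$sigma_J
  cat(sprintf("  couplings with |J| > 2 sigma_J: %d of %d\n",
              sum(sig), nrow(x$couplings)))
  cat("  leading couplings:\n")
  print(utils::head(x$couplings, 8L), row.names = FALSE, digits = 3)
  if (x$n_not_converged > 0L)
    cat("  note:", x$n_not_converged, "batch fit(s) hit max_epochs\n")
  invisible(x)
}

#' @export
coef.maxent_pairwise <- function(object, ...) {
  stats::setNames(c(object$h, object$J),
                  c("h", paste0("J", seq_len(object$max_lag))))
}

#' @export
plot.maxent_pairwise <- function(x, log = FALSE, ...) {
  tau <- seq_len(x$max_lag)
  if (log) {
    keep <- abs(x$J) > 0
    graphics::plot(tau[keep], abs(x$J)[keep], log = "xy",
                   xlab = expression(tau), ylab = expression(abs(J(tau))),
                   pch = 16, col = "firebrick", ...)
  } else {
    graphics::plot(tau, x$J, xlab = expression(tau),
                   ylab = expression(J(tau)), pch = 16, col = "firebrick",
                   ...)
    if (any(x$sigma_J > 0))
      graphics::arrows(tau, x$J - x$sigma_J, tau, x$J + x$sigma_J,
                       angle = 90, code = 3, length = 0.02, col = "grey50")
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' One-step conditional means under a fitted model
#'
#' For each window position of `newdata`, the conditional mean
#' `h + sum_tau J(tau) z[t - tau]` of the next standardized value.
#'
#' @param object a fitted [maxent_pairwise()] model (or [coupling_model()]).
#' @param newdata a standardized series longer than the model order.
#' @param ... unused.
#' @return numeric vector of length `length(newdata) - max_lag`, the
#'   predicted values for positions `max_lag + 1 .. N`.
#' @export
predict.coupling_model <- function(object, newdata, ...) {
  zv <- as.numeric(newdata)
  zv[(object$max_lag + 1L):length(zv)] -
    one_step_residuals(zv, object$J, object$h)
}

#' One-step prediction residuals
#'
#' @inheritParams predict.coupling_model
#' @return numeric vector `z[t] - predicted[t]` for
#'   `t = max_lag + 1 .. N`; under the model these are approximately
#'   standard normal innovations.
#' @export
residuals.coupling_model <- function(object, newdata, ...) {
  one_step_residuals(as.numeric(newdata), object$J, object$h)
}

#' Simulate from a coupling model
#'
#' Draws standardized series from the model's generative conditional:
#' autoregressive sampling with unit-variance Gaussian innovations (see
#' [sample_autoregressive()]).
#'
#' @param object a [coupling_model()].
#' @param nsim number of series.
#' @param seed integer seed (required, for reproducibility).
#' @param n length of each series.
#' @param burn_in discarded initial samples (at least the model order).
#' @param ... unused.
#' @return a list of `"std_series"` (or a single one if `nsim = 1`).
#' @export
simulate.coupling_model <- function(object, nsim = 1, seed = NULL,
                                    n = 10000L, burn_in = NULL, ...) {
  if (is.null(seed)) stop("simulate() needs an explicit integer seed")
  out <- lapply(seq_len(nsim), function(k)
    sample_autoregressive(object, n = n, seed = seed + k - 1L,
                          burn_in = burn_in))
  if (nsim == 1L) out[[1L]] else out
}
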