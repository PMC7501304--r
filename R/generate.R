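#' Noise-perturbed couplings
#'
#' Draws a noisy realization of the inferred couplings,
#' `Jbar(tau) = J(tau) + eta_tau * sigma_J(tau)` with independent
#' standard-normal `eta_tau`. One draw is used per generated synthetic
#' series, so the coupling uncertainty propagates into an ensemble of
#' syntheses.
#'
#' @param model a [coupling_model()] with `sigma_J` populated.
#' @param seed integer seed for the perturbation draw.
#' @return list of class `"noisy_couplings"`: `J_bar`, `h`, `max_lag`,
#'   `seed`.
#' @export
perturb_couplings <- function(model, seed) {
  eta <- local_seed(seed, stats::rnorm(model$max_lag))
  structure(list(J_bar = model$J + eta * model$sigma_J, h = model$h,
                 max_lag = model$max_lag, seed = seed),
            class = "noisy_couplings")
}

#' Generate a synthetic series by sliding-window convolution
#'
#' Implements the one-step conditional mode read along the experimental
#' series: every window of `T` consecutive experimental values is
#' convolved with the couplings and the bias added,
#' `ztilde_n = sum_tau Jbar(tau) z[T + n - tau] + h`, for
#' `n = 1 .. N - T`. No innovation noise is added; stochasticity enters
#' only through the coupling perturbation. The window always reads the
#' *experimental* series (a linear filtering of the seed), never the
#' synthetic one.
#'
#' @param seed_series experimental standardized series of length `> T`.
#' @param couplings a `"noisy_couplings"` object (or a
#'   [coupling_model()], whose exact `J` is then used).
#' @param h bias; defaults to the value stored in `couplings`.
#' @return numeric vector of length `N - T` (not yet standardized; see
#'   [finalize_synthetic()]).
#' @export
convolve_generate <- function(seed_series, couplings, h = NULL) {
  J <- if (inherits(couplings, "noisy_couplings")) couplings$J_bar
       else couplings$J
  if (is.null(h)) h <- couplings$h
  zv <- as.numeric(seed_series)
  T_ <- length(J)
  if (length(zv) <= T_)
    stop("seed series must be longer than the coupling cutoff")
  acc <- stats::filter(zv, c(0, J), method = "convolution", sides = 1)
  as.numeric(acc[(T_ + 1L):length(zv)]) + h
}

#' Standardize a raw synthetic series
#'
#' Convolution output is centered near zero but not standardized; this
#' applies the same zero-mean, unit-second-moment standardization used
#' for experimental tachograms.
#'
#' @param raw numeric vector (length at least 2, nonzero variance).
#' @param patient_id,class_label metadata for the result.
#' @return a `"std_series"`.
#' @export
finalize_synthetic <- function(raw, patient_id = "synthetic",
                               class_label = "UNKNOWN") {
  std_series(as.numeric(raw), patient_id = patient_id,
             class_label = class_label)
}

#' Convolution-based synthetic series from a fitted model
#'
#' Convenience pipeline: [perturb_couplings()] (one draw) then
#' [convolve_generate()] then [finalize_synthetic()].
#'
#' @param model a [coupling_model()] with `sigma_J`.
#' @param seed_series experimental standardized series used as seed.
#' @param seed integer seed for the coupling perturbation.
#' @return a `"std_series"` of length `length(seed_series) - max_lag`.
#' @export
generate_series <- function(model, seed_series, seed) {
  nc <- perturb_couplings(model, seed)
  finalize_synthetic(
    convolve_generate(seed_series, nc),
    patient_id = paste0(attr(seed_series, "patient_id") %||% "seed", "_synth"),
    class_label = model$class_label)
}
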