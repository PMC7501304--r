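#' Class presets for the synthetic-data generator
#'
#' Best-fit power-law parameters of the coupling-magnitude decay for
#' the three clinical classes (healthy `H`: A = 0.38, beta = 1.41;
#' atrial fibrillation `AF`: A = 0.20, beta = 0.96; cardiac
#' decompensation `CD`: A = 0.37, beta = 1.2), together with default
#' series length and the physical scale used when wrapping standardized
#' samples back into milliseconds.
#'
#' @param class_label `"H"`, `"AF"` or `"CD"`.
#' @return list of class `"class_preset"`: `class_label`, `A`, `beta`,
#'   `n_beats`, `mean_ms`, `std_ms`.
#' @export
class_preset <- function(class_label = c("H", "AF", "CD")) {
  class_label <- match.arg(toupper(class_label), c("H", "AF", "CD"))
  p <- switch(class_label,
              H  = list(A = 0.38, beta = 1.41),
              AF = list(A = 0.20, beta = 0.96),
              CD = list(A = 0.37, beta = 1.2))
  structure(list(class_label = class_label, A = p$A, beta = p$beta,
                 n_beats = 20000L, mean_ms = 800, std_ms = 50),
            class = "class_preset")
}

companion_radius <- function(J) {
  T_ <- length(J)
  if (T_ == 1L) return(abs(J))
  Cm <- rbind(J, cbind(diag(1, T_ - 1L), 0))
  max(Mod(eigen(Cm, only.values = TRUE)$values))
}

#' Plant power-law couplings
#'
#' Builds a ground-truth coupling vector with magnitudes
#' `A * tau^(-beta)` and a chosen sign structure (iid random signs by
#' default, allowing frustration). If the implied autoregressive
#' process is not stationary (companion-matrix spectral radius >= 1),
#' the couplings are rescaled by `0.95 / rho` repeatedly until it is;
#' the final rescale factor is recorded so recovery checks compare
#' against the rescaled truth. Rescaling changes `A` but never `beta`.
#'
#' @param preset a [class_preset()], or `NULL` to pass `A`, `beta`
#'   directly.
#' @param max_lag coupling cutoff T.
#' @param sign_scheme `"random"`, `"alternating"` or `"all_positive"`.
#' @param seed integer seed for the random sign draw (`NULL` uses the
#'   current RNG state).
#' @param A,beta power-law parameters when `preset` is `NULL`.
#' @param h bias of the planted model (default 0).
#' @param scale_to_radius optional target companion spectral radius in
#'   `(0, 1)`: the couplings are rescaled by a single factor so the
#'   radius hits this value. Radii close to 1 emulate the strongly
#'   persistent, low-frequency-dominated correlation regime of
#'   recorded tachograms.
#' @return object of class `c("planted_model", "coupling_model")` with
#'   extra fields `A` (after rescaling), `A_requested`, `beta`,
#'   `sign_scheme`, `rescale_factor`, `spectral_radius`.
#' @export
planted_couplings <- function(preset = NULL, max_lag = 100L,
                              sign_scheme = c("random", "alternating",
                                              "all_positive"),
                              seed = NULL, A = NULL, beta = NULL, h = 0,
                              scale_to_radius = NULL) {
  sign_scheme <- match.arg(sign_scheme)
  if (!is.null(preset)) {
    A <- preset$A; beta <- preset$beta
    class_label <- preset$class_label
  } else {
    if (is.null(A) || is.null(beta)) stop("give a preset or both A and beta")
    class_label <- "UNKNOWN"
  }
  tau <- seq_len(max_lag)
  mag <- A * tau^(-beta)
  signs <- switch(sign_scheme,
                  random = local_seed(seed,
                    sample(c(-1, 1), max_lag, replace = TRUE)),
                  alternating = (-1)^(tau + 1),
                  all_positive = rep(1, max_lag))
  J <- mag * signs
  rescale <- 1
  rho <- companion_radius(J)
  if (!is.null(scale_to_radius)) {
    stopifnot(scale_to_radius > 0, scale_to_radius < 1)
    # the radius grows continuously (and slowly, for tail-dominated J)
    # with a scalar rescaling; bracket the target adaptively
    upper <- 1
    it <- 0L
    while (companion_radius(J * upper) < scale_to_radius && it < 60L) {
      upper <- upper * 2; it <- it + 1L
    }
    fct <- stats::uniroot(function(c0)
      companion_radius(J * c0) - scale_to_radius,
      lower = upper * 1e-9, upper = upper, tol = 1e-10)$root
    J <- J * fct
    rescale <- fct
    rho <- companion_radius(J)
  }
  while (rho >= 1) {
    fct <- 0.95 / rho
    J <- J * fct
    rescale <- rescale * fct
    rho <- companion_radius(J)
  }
  out <- coupling_model(J, h = h, class_label = class_label)
  out$A <- A * rescale
  out$A_requested <- A
  out$beta <- beta
  out$sign_scheme <- sign_scheme
  out$rescale_factor <- rescale
  out$spectral_radius <- rho
  class(out) <- c("planted_model", class(out))
  out
}

#' Sample the model autoregressively
#'
#' Draws a standardized series from the model's generative conditional:
#' `z_t = h + sum_tau J(tau) z_{t-tau} + eps_t` with iid standard-normal
#' innovations, discarding a burn-in and standardizing the result. This
#' is the model's true sampler, kept distinct from the convolution
#' procedure of [convolve_generate()].
#'
#' @param model a [coupling_model()] (must be stationary: companion
#'   spectral radius `< 1`).
#' @param n output length after burn-in.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @param burn_in discarded initial steps; default
#'   `max(1000, 10 * max_lag)`, never below the model order.
#' @param patient_id identifier for the resulting series.
#' @return a `"std_series"` of length `n`.
#' @export
sample_autoregressive <- function(model, n, seed = NULL, burn_in = NULL,
                                  patient_id = "ar_sample") {
  T_ <- model$max_lag
  if (is.null(burn_in)) burn_in <- max(1000L, 10L * T_)
  burn_in <- max(as.integer(burn_in), T_)
  if (n < 2L) stop("n must be at least 2")
  rho <- companion_radius(model$J)
  if (rho >= 1)
    stop("non-stationary model: companion spectral radius ", signif(rho, 4))
  eps <- local_seed(seed, stats::rnorm(n + burn_in))
  x <- stats::filter(eps + model$h, model$J, method = "recursive")
  std_series(as.numeric(x)[(burn_in + 1L):(burn_in + n)],
             patient_id = patient_id, class_label = model$class_label)
}

#' Wrap a standardized series into physical units
#'
#' Inverse of [standardize()]: `r_n = z_n * std_ms + mean_ms`, giving a
#' positive RR tachogram in milliseconds.
#'
#' @param z a `"std_series"` (or numeric vector).
#' @param mean_ms,std_ms target mean and standard deviation (ms);
#'   `mean_ms` should exceed about `4 * std_ms` so all intervals stay
#'   positive.
#' @param patient_id,class_label metadata for the RR series; default to
#'   the attributes of `z`.
#' @return an [rr_series()].
#' @export
make_raw_rr <- function(z, mean_ms = 800, std_ms = 50,
                        patient_id = NULL, class_label = NULL) {
  r <- as.numeric(z) * std_ms + mean_ms
  if (any(r <= 0))
    stop("nonpositive interval produced; increase mean_ms or decrease std_ms")
  rr_series(r,
            patient_id = patient_id %||% attr(z, "patient_id") %||% "synthetic",
            class_label = class_label %||% attr(z, "class_label") %||% "UNKNOWN")
}

#' Gaussian noise with a planted power-law spectrum
#'
#' Builds a series whose power spectrum is exactly proportional to
#' `f^(-gamma)` (DC removed): deterministic spectral amplitudes with
#' independent uniform random phases, transformed back to the time
#' domain. Superposing thousands of random-phase harmonics makes the
#' marginal Gaussian to high accuracy, while the planted spectrum
#' carries no amplitude fluctuation — an independent fixture with a
#' known exponent for validating [fit_psd_power_law()].
#'
#' @param gamma spectral exponent in `[0, 2]`.
#' @param n series length, a power of two `>= 1024`.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return a `"std_series"` of length `n`.
#' @export
spectral_shaped_noise <- function(gamma, n, seed = NULL) {
  if (gamma < 0 || gamma > 2)
    stop("gamma must lie in [0, 2] for this fixture")
  n <- as.integer(n)
  if (n < 1024L || bitwAnd(n, n - 1L) != 0L)
    stop("n must be a power of two, at least 2^10")
  half <- n %/% 2L
  draws <- local_seed(seed, stats::runif(half))
  f <- (1:half) / n
  amp <- f^(-gamma / 2)
  X <- complex(length.out = n)                      # X[1] = DC = 0
  phases <- exp(2i * pi * draws[-half])
  X[2:half] <- amp[-half] * phases
  X[half + 1L] <- amp[half] * sign(draws[half] - 0.5) # Nyquist, real
  X[(half + 2L):n] <- Conj(X[half:2])
  z <- Re(stats::fft(X, inverse = TRUE)) / n
  std_series(z, patient_id = sprintf("shaped_gamma%.2g", gamma))
}

#' Emit a synthetic labelled cohort
#'
#' Emulates the structure of a labelled Holter cohort: for each class
#' and patient, plants couplings from the class preset (per-patient
#' sign seed by default), samples the model autoregressively, wraps the
#' series in milliseconds, and writes an RR text file. A manifest CSV
#' and a JSON file of planted truths are written alongside.
#'
#' @param out_dir output directory (created if needed).
#' @param presets list of [class_preset()] objects (default all three
#'   classes).
#' @param patients_per_class series per class.
#' @param n_beats series length.
#' @param max_lag planted coupling cutoff.
#' @param seed integer master seed; per-patient seeds derive from it.
#' @param shared_signs if `TRUE`, all patients of a class share one
#'   sign realization (one planted model per class).
#' @return the manifest (as from [read_manifest()]); attribute
#'   `truths_path` gives the JSON of planted truths.
#' @export
make_dataset <- function(out_dir, presets = lapply(c("H", "AF", "CD"),
                                                   class_preset),
                         patients_per_class = 2L, n_beats = 5000L,
                         max_lag = 50L, seed = 1L, shared_signs = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_total <- length(presets) * patients_per_class
  sub_seeds <- local_seed(seed,
    matrix(sample.int(.Machine$integer.max, 2L * n_total), ncol = 2L))
  records <- list(); truths <- list()
  k <- 0L
  for (preset in presets) {
    class_model <- NULL
    for (j in seq_len(patients_per_class)) {
      k <- k + 1L
      pid <- sprintf("%s%03d", preset$class_label, j)
      sign_seed <- sub_seeds[k, 1L]
      pm <- if (shared_signs && !is.null(class_model)) class_model else
        planted_couplings(preset, max_lag = max_lag, sign_scheme = "random",
                          seed = sign_seed)
      if (shared_signs) class_model <- pm
      z <- sample_autoregressive(pm, n_beats, seed = sub_seeds[k, 2L],
                                 patient_id = pid)
      rr <- make_raw_rr(z, preset$mean_ms, preset$std_ms, patient_id = pid)
      fn <- paste0(pid, ".txt")
      write_rr(rr, file.path(out_dir, fn),
               header = paste("synthetic", preset$class_label))
      records[[k]] <- data.frame(patient_id = pid,
                                 class = preset$class_label, path = fn)
      truths[[pid]] <- list(J_true = pm$J, h_true = pm$h,
                            A = pm$A, beta = pm$beta,
                            rescale_factor = pm$rescale_factor,
                            sign_seed = sign_seed)
    }
  }
  manifest_path <- file.path(out_dir, "manifest.csv")
  write_manifest(do.call(rbind, records), manifest_path)
  truths_path <- file.path(out_dir, "truths.json")
  jsonlite::write_json(truths, truths_path, auto_unbox = TRUE, digits = NA)
  out <- read_manifest(manifest_path)
  attr(out, "truths_path") <- truths_path
  out
}
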