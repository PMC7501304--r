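#' Compare two samples through their empirical CDFs
#'
#' Evaluates both empirical cumulative distribution functions on the
#' pooled support, reports their maximal absolute difference, and
#' checks whether `sample_b`'s ECDF lies inside a level-`p`
#' distribution-free band around `sample_a`'s ECDF. The half-width is
#' the Dvoretzky-Kiefer-Wolfowitz bound applied to the *difference* of
#' two finite-sample ECDFs,
#' `eps = sqrt(log(2 / (1 - p)) / 2) * sqrt(1/m_a + 1/m_b)`,
#' which reduces to the classical one-sample DKW band when the
#' comparison sample is much larger than the reference (its ECDF then
#' standing in for the population CDF), and is calibrated for two
#' samples of comparable size.
#'
#' @param sample_a reference sample (band is built around its ECDF).
#' @param sample_b comparison sample.
#' @param p band confidence level.
#' @return list of class `"ecdf_report"`: `distance` (max absolute
#'   ECDF difference), `p`, `epsilon` (band half-width),
#'   `fraction_inside` (fraction of evaluation points inside the
#'   band), `pass` (`TRUE` when every point is inside).
#' @export
ecdf_compare <- function(sample_a, sample_b, p = 0.95) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  x <- sort(c(a, b))
  Fa <- stats::ecdf(a)(x)
  Fb <- stats::ecdf(b)(x)
  d <- abs(Fa - Fb)
  eps <- sqrt(log(2 / (1 - p)) / 2) * sqrt(1 / length(a) + 1 / length(b))
  frac <- mean(d <= eps)
  structure(list(distance = max(d), p = p, epsilon = eps,
                 fraction_inside = frac, pass = max(d) <= eps),
            class = "ecdf_report")
}

#' @export
print.ecdf_report <- function(x, ...) {
  cat(sprintf("ECDF comparison: distance %.4f, DKW band %.4f (p = %.2f), %.1f%% inside -> %s\n",
              x$distance, x$epsilon, x$p, 100 * x$fraction_inside,
              if (x$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Probability-plot pairs of two samples
#'
#' `(F_a(x), F_b(x))` evaluated on the pooled sorted support: the
#' cumulative-vs-cumulative pairs of a probability plot. Identical
#' samples fall on the identity line.
#'
#' @inheritParams ecdf_compare
#' @return data frame with columns `x`, `F_a`, `F_b`, sorted by `x`.
#' @export
probability_plot_points <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  x <- sort(c(a, b))
  data.frame(x = x, F_a = stats::ecdf(a)(x), F_b = stats::ecdf(b)(x))
}

#' Autocorrelation confidence band of synthetic ensembles
#'
#' Generates `n_synth` convolution-based syntheses from one seed series
#' (each with a fresh noisy-coupling draw), computes their
#' autocorrelation functions, and summarizes them as a pointwise median
#' and central level-`p` percentile band. The seed series' own
#' autocorrelation is then checked against the band; since the band is
#' pointwise, coverage at 95% of the lags counts as inside.
#'
#' @param seed_series experimental `"std_series"` (longer than the
#'   model order).
#' @param model [coupling_model()] with `sigma_J` populated.
#' @param n_synth ensemble size.
#' @param p central band level (default 0.68, i.e. 16th-84th
#'   percentiles).
#' @param lag_max largest autocorrelation lag.
#' @param seed integer base seed for the perturbation draws.
#' @param coverage fraction of lags required inside the band.
#' @return list of class `"autocorr_band"`: `lags`, `median`, `lower`,
#'   `upper`, `reference` (seed series' autocorrelation), `coverage`
#'   (fraction of lags inside), `pass`, `n_synth`, `p`.
#' @export
autocorrelation_band <- function(seed_series, model, n_synth = 100L,
                                 p = 0.68, lag_max = 100L, seed = 1L,
                                 coverage = 0.95) {
  acfs <- vapply(seq_len(n_synth), function(j) {
    zs <- generate_series(model, seed_series, seed = seed + j - 1L)
    autocorrelation(zs, lag_max)$C
  }, numeric(lag_max + 1L))
  acfs <- matrix(acfs, nrow = lag_max + 1L)
  lo <- apply(acfs, 1L, stats::quantile, probs = (1 - p) / 2, names = FALSE)
  hi <- apply(acfs, 1L, stats::quantile, probs = (1 + p) / 2, names = FALSE)
  md <- apply(acfs, 1L, stats::median)
  ref <- autocorrelation(seed_series, lag_max)$C
  tol <- 1e-12
  inside <- ref >= lo - tol & ref <= hi + tol
  structure(list(lags = 0:lag_max, median = md, lower = lo, upper = hi,
                 reference = ref, coverage = mean(inside),
                 pass = mean(inside) >= coverage,
                 n_synth = n_synth, p = p),
            class = "autocorr_band")
}

#' @export
print.autocorr_band <- function(x, ...) {
  cat(sprintf("autocorrelation band (p = %.2f, %d syntheses): %.1f%% of lags covered -> %s\n",
              x$p, x$n_synth, 100 * x$coverage,
              if (x$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Recovery diagnostics against a planted truth
#'
#' Compares an inferred coupling model with the planted ground truth:
#' per-lag z-scores `(J - J_true) / sigma_J`, the RMSE of the leading
#' couplings, and (when a tail fit is supplied) the error of the
#' recovered power-law exponent.
#'
#' @param truth a `"planted_model"` (or any [coupling_model()] whose
#'   `J` is the truth; a `beta` field, if present, is used for the
#'   exponent error).
#' @param inferred the fitted [maxent_pairwise()] model.
#' @param fit optional [fit_power_law_tail()] result on `inferred`.
#' @param rmse_lags lags over which the RMSE is computed (default 1..20).
#' @return list of class `"recovery_report"`: `zscores`, `rmse_J`,
#'   `zscore_exceed_frac` (fraction with |z| > 2), `beta_hat`,
#'   `beta_true`, `beta_err`.
#' @export
recovery_report <- function(truth, inferred, fit = NULL,
                            rmse_lags = 1:20) {
  if (is.null(truth$J)) stop("missing planted truth")
  T_ <- min(length(truth$J), inferred$max_lag)
  dJ <- inferred$J[1:T_] - truth$J[1:T_]
  z <- ifelse(inferred$sigma_J[1:T_] > 0, dJ / inferred$sigma_J[1:T_],
              ifelse(dJ == 0, 0, Inf))
  rl <- rmse_lags[rmse_lags <= T_]
  beta_true <- truth$beta %||% NA_real_
  beta_hat <- if (!is.null(fit)) fit$beta else NA_real_
  structure(list(zscores = z,
                 rmse_J = sqrt(mean(dJ[rl]^2)),
                 zscore_exceed_frac = mean(abs(z) > 2),
                 beta_hat = beta_hat, beta_true = beta_true,
                 beta_err = beta_hat - beta_true),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery: RMSE(J, leading lags) = %.4g; |z| > 2 at %.1f%% of lags\n",
              x$rmse_J, 100 * x$zscore_exceed_frac))
  if (!is.na(x$beta_hat))
    cat(sprintf("  beta_hat = %.3f vs planted %.3f (error %+.3f)\n",
                x$beta_hat, x$beta_true, x$beta_err))
  invisible(x)
}

#' End-to-end power-law recovery experiment
#'
#' The package's end-to-end recovery benchmark: plant class-preset
#' couplings with random signs (stationarity
#' enforced), sample a cohort of series from the model, run resampled
#' pseudo-likelihood inference, fit the coupling-magnitude tail, and
#' report the recovered exponent against the planted one.
#'
#' @param preset a [class_preset()] (or class label string).
#' @param n_series cohort size.
#' @param n_beats beats per series.
#' @param max_lag inference cutoff T.
#' @param lambda regularization weight.
#' @param plan a [resample_plan()].
#' @param control an [adagrad_control()].
#' @param seed integer master seed.
#' @return list with the planted model (`truth`), fitted model (`fit`),
#'   tail fit (`tail`), recovery report (`recovery`), and `beta_hat`,
#'   `beta_true`.
#' @export
beta_recovery_experiment <- function(preset, n_series = 40L,
                                     n_beats = 20000L, max_lag = 100L,
                                     lambda = 1e-2,
                                     plan = resample_plan(50L, 8L),
                                     control = adagrad_control(),
                                     seed = 1L) {
  if (is.character(preset)) preset <- class_preset(preset)
  seeds <- local_seed(seed, sample.int(.Machine$integer.max, n_series + 2L))
  truth <- planted_couplings(preset, max_lag = max_lag,
                             sign_scheme = "random", seed = seeds[1L])
  series <- lapply(seq_len(n_series), function(i)
    sample_autoregressive(truth, n_beats, seed = seeds[i + 2L],
                          patient_id = sprintf("%s%03d",
                                               preset$class_label, i)))
  fit <- maxent_pairwise(series, max_lag = max_lag, lambda = lambda,
                         resample = plan, control = control,
                         seed = seeds[2L], class_label = preset$class_label)
  tail_fit <- fit_power_law_tail(fit)
  rec <- recovery_report(truth, fit, tail_fit)
  list(truth = truth, fit = fit, tail = tail_fit, recovery = rec,
       beta_hat = tail_fit$beta, beta_true = preset$beta,
       n_series = n_series, n_beats = n_beats)
}
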