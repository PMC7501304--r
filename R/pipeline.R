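#' Pipeline configuration
#'
#' Bundles every tunable of the analysis pipeline; values mirror the
#' package defaults and can be saved to / loaded from JSON.
#'
#' @param max_lag coupling cutoff T.
#' @param lambda regularization weight.
#' @param learn_rate,epsilon,max_epochs,tol AdaGrad settings (see
#'   [adagrad_control()]).
#' @param n_batches,batch_size resampling plan (see [resample_plan()]).
#' @param seed integer master seed.
#' @param segment_length,overlap Welch PSD settings.
#' @param fit_band PSD fit band, cycles per beat.
#' @param lag_max autocorrelation lag window for validation.
#' @param n_synth syntheses per validation ensemble.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(max_lag = 100L, lambda = 1e-2,
                            learn_rate = 0.05, epsilon = 1e-8,
                            max_epochs = 500L, tol = 1e-6,
                            n_batches = 50L, batch_size = 8L,
                            seed = 1L, segment_length = 4096L,
                            overlap = 0.5, fit_band = c(1e-4, 1e-2),
                            lag_max = 100L, n_synth = 100L) {
  structure(list(max_lag = as.integer(max_lag), lambda = lambda,
                 control = adagrad_control(learn_rate, epsilon,
                                           max_epochs, tol),
                 plan = resample_plan(n_batches, batch_size),
                 seed = as.integer(seed),
                 segment_length = as.integer(segment_length),
                 overlap = overlap, fit_band = fit_band,
                 lag_max = as.integer(lag_max),
                 n_synth = as.integer(n_synth)),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config`
#'   returns a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  flat <- list(max_lag = config$max_lag, lambda = config$lambda,
               learn_rate = config$control$learn_rate,
               epsilon = config$control$epsilon,
               max_epochs = config$control$max_epochs,
               tol = config$control$tol,
               n_batches = config$plan$n_batches,
               batch_size = config$plan$batch_size,
               seed = config$seed,
               segment_length = config$segment_length,
               overlap = config$overlap, fit_band = config$fit_band,
               lag_max = config$lag_max, n_synth = config$n_synth)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  flat <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, flat)
}

pipeline_stage <- function(name, quiet, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  if (!quiet)
    message(sprintf("[%s] done in %.1f s", name,
                    proc.time()[["elapsed"]] - t0))
  res
}

#' Run the whole analysis pipeline for one class
#'
#' Standardize the class' RR series, run resampled pseudo-likelihood
#' inference, fit the coupling-magnitude tail, generate a
#' convolution-based synthetic ensemble, estimate spectral exponents,
#' and validate distributions and autocorrelation. Writes
#' `couplings_<class>.csv` (columns `tau,J,sigma_J`) and
#' `report_<class>.json` into `out_dir`.
#'
#' @param manifest a `"dataset_manifest"` (or path to a manifest CSV).
#' @param class_label class to analyse (`"H"`, `"AF"`, `"CD"`).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage messages.
#' @return (invisibly) list with `model`, `tail`, `spectral`,
#'   `validation`, and the paths of the written artifacts.
#' @export
run_pipeline <- function(manifest, class_label, config = pipeline_config(),
                         out_dir = ".", quiet = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!quiet)
    message(sprintf("pipeline: class %s, T = %d, lambda = %.3g, seed = %d",
                    class_label, config$max_lag, config$lambda, config$seed))

  series <- pipeline_stage("standardize", quiet, {
    rrs <- load_class_series(manifest, class_label)
    lapply(rrs, standardize)
  })

  model <- pipeline_stage("infer", quiet,
    maxent_pairwise(series, max_lag = config$max_lag,
                    lambda = config$lambda, resample = config$plan,
                    control = config$control, seed = config$seed,
                    class_label = class_label))

  tail_fit <- pipeline_stage("fit-tail", quiet, fit_power_law_tail(model))

  seed_series <- series[[1L]]
  synth <- pipeline_stage("generate", quiet,
    lapply(seq_len(config$n_synth), function(j)
      generate_series(model, seed_series, seed = config$seed + j)))

  spectral <- pipeline_stage("psd", quiet, {
    seg <- min(config$segment_length,
               2^floor(log2(length(seed_series) / 4)))
    g_exp <- fit_psd_power_law(
      welch_psd(seed_series, seg, config$overlap), config$fit_band)
    g_syn <- vapply(synth, function(zs)
      fit_psd_power_law(welch_psd(zs, min(seg, 2^floor(log2(length(zs) / 4))),
                                  config$overlap), config$fit_band)$gamma,
      numeric(1))
    list(gamma_experimental = g_exp$gamma,
         sigma_gamma_experimental = g_exp$sigma_gamma,
         gamma_synthetic_mean = mean(g_syn),
         gamma_synthetic_sd = stats::sd(g_syn))
  })

  validation <- pipeline_stage("validate", quiet, {
    fresh <- sample_autoregressive(model, n = length(synth[[1L]]),
                                   seed = config$seed + config$n_synth + 1L)
    ec <- ecdf_compare(as.numeric(fresh), as.numeric(synth[[1L]]))
    ab <- autocorrelation_band(seed_series, model,
                               n_synth = config$n_synth,
                               lag_max = min(config$lag_max,
                                             length(synth[[1L]]) %/% 10L),
                               seed = config$seed)
    list(ecdf = list(distance = ec$distance, p = ec$p, pass = ec$pass),
         autocorr = list(p = ab$p, coverage = ab$coverage,
                         n_synth = ab$n_synth, pass = ab$pass))
  })

  couplings_path <- file.path(out_dir,
                              sprintf("couplings_%s.csv", class_label))
  utils::write.csv(data.frame(tau = seq_len(model$max_lag), J = model$J,
                              sigma_J = model$sigma_J),
                   couplings_path, row.names = FALSE, quote = FALSE)
  report <- list(
    class_label = class_label,
    n_series = model$n_series,
    config = list(max_lag = config$max_lag, lambda = config$lambda,
                  n_batches = config$plan$n_batches,
                  batch_size = config$plan$batch_size, seed = config$seed),
    h = model$h, sigma_h = model$sigma_h,
    n_not_converged = model$n_not_converged,
    tail_fit = list(A = tail_fit$A, beta = tail_fit$beta,
                    sigma_A = tail_fit$sigma_A,
                    sigma_beta = tail_fit$sigma_beta,
                    tau_lo = tail_fit$tau_lo, tau_hi = tail_fit$tau_hi,
                    adj_r2 = tail_fit$adj_r2,
                    chi2_dof = tail_fit$chi2_dof,
                    n_excluded = tail_fit$n_excluded),
    spectral = spectral,
    validation = validation)
  report_path <- file.path(out_dir, sprintf("report_%s.json", class_label))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)

  invisible(list(model = model, tail = tail_fit, spectral = spectral,
                 validation = validation,
                 couplings_path = couplings_path,
                 report_path = report_path))
}
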