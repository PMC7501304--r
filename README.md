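# glassyhrv

Maximum-entropy pairwise ("glassy") modelling of heart-rate variability
in R.

## The problem

Heart-rate variability (HRV) is read off the RR tachogram — the sequence
of intervals between consecutive heartbeats in a long (e.g. 24 h Holter)
recording. Healthy hearts show 1/f-like fluctuations; pathologies such
as atrial fibrillation (AF) or congestive heart failure / cardiac
decompensation (CD) distort them. `glassyhrv` models a standardized
tachogram `z` with the least-structured (maximum-entropy) probability
distribution whose first and second moments match the data. With a
standard-normal prior per beat this is a Gaussian pairwise model

    P(z) ∝ [ Π_n P0(z_n) ] · exp( Σ_n Σ_τ J(τ) z_n z_{n+τ} + h Σ_n z_n )

whose parameters are long-range delayed couplings `J(τ)` (τ = 1..T beats
apart) and a bias `h` (≈ 0 after standardization). Because the coupling
between beats at the same distance can be positive or negative
("frustration"), the model is formally a one-dimensional spin glass with
quenched power-law interactions: the coupling magnitudes decay as

    |J(τ)| ~ A · τ^(−β),

with β near 1, and the exponent differs between clinical classes —
making β a candidate HRV biomarker.

The package is aimed at researchers in computational physiology and
statistical inference who want a tested, reproducible implementation of
this pipeline: inference of `J(τ)` and `h`, power-law summarization of
the coupling decay, model-based generation of synthetic tachograms, and
distributional / autocorrelation / spectral validation.

## What it computes

- **Inference** (`maxent_pairwise()`): the full likelihood is
  intractable (its partition function never needs to be evaluated), so
  the model is fitted by maximizing a sliding-window Gaussian
  *pseudo-likelihood* — the average one-step conditional log-density
  `−(1/(2(N−T))) Σ_L (z_{L+1} − h − Σ_τ J(τ) z_{L+1−τ})²` — with ridge
  penalties `(λ/2)h²` and `(λ/2) Σ_τ log²(1+τ) J(τ)²`, by AdaGrad
  ascent. Uncertainties `σ_J, σ_h` come from refitting on many random
  patient subsets (minibatch resampling) and taking across-subset
  standard deviations.
- **Tail fit** (`fit_power_law_tail()`): weighted least squares of
  `|J(τ)|` against `A·τ^(−β)` (weights `1/σ_J²`), the fit range chosen
  to maximize the adjusted R², with reduced χ² and normalized residual
  diagnostics.
- **Generation** (`generate_series()`): synthetic standardized series by
  sliding-window convolution of an experimental seed series with
  noise-perturbed couplings `J̄(τ) = J(τ) + η σ_J(τ)`; the model's exact
  autoregressive sampler (`sample_autoregressive()`, `simulate()`) is
  kept distinct.
- **Validation** (`ecdf_compare()`, `autocorrelation_band()`,
  `welch_psd()` + `fit_psd_power_law()`): ECDF distance with
  distribution-free confidence bands, autocorrelation percentile bands
  over synthetic ensembles, and Welch power-spectral-density slope
  `PSD(f) ~ α·f^(−γ)` in the low-frequency band.
- **Synthetic ground truth** (`planted_couplings()`, `make_dataset()`):
  plants class-specific power-law couplings (H, AF, CD presets), samples
  the model, and wraps series back into milliseconds, so the whole
  pipeline can be validated by parameter recovery.

## Worked example

Plant AF-class couplings (`|J| = 0.20·τ^(−0.96)`, random signs), sample
40 series of 20,000 beats, infer with 50 minibatches of 8 patients, and
fit the coupling-magnitude tail:

```r
library(glassyhrv)
ex <- beta_recovery_experiment("AF", seed = 1)
ex$fit
#> maximum-entropy pairwise model [AF]
#>   40 series, T = 100, lambda = 0.01
#>   resampled: 50 batches of 8
#>   h = -7.777e-05 (sigma 0.00014)
#>   J(1..5): 0.1998, 0.1023, 0.06714, -0.04918, -0.04153 ...
ex$tail
#> power-law tail fit |J(tau)| ~ A * tau^-beta on [1, 100]
#>   A    = 0.2007 +/- 0.0025
#>   beta = 0.9965 +/- 0.01
#>   adjusted R^2 = 0.997, chi^2/DOF = 0.264 (100 points, 0 zero(s) excluded)
ex$recovery
#> recovery: RMSE(J, leading lags) = 0.001602; |z| > 2 at 0.0% of lags
#>   beta_hat = 0.997 vs planted 0.960 (error +0.037)
```

The bias comes back at ~1e−4 (standardization makes it vanish), the
leading couplings match the planted values within their uncertainties,
and the recovered decay exponent is within 0.04 of the planted 0.96.
Spectral slopes are recovered the same way:

```r
z <- spectral_shaped_noise(1, 2^17, seed = 1)   # planted 1/f noise
fit_psd_power_law(welch_psd(z, 4096))
#> PSD power-law fit: gamma = 0.998 +/- 0.011 over [0.00024, 0.0098] cycles/beat (40 bins)
```

For file-based cohorts (one RR text file per patient plus a
`patient_id,class,path` manifest), `run_pipeline(manifest, "H")` chains
standardize → infer → tail fit → generate → PSD → validate and writes a
couplings CSV and a JSON report.

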