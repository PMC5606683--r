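# maxexposure

Deterministic modelling of short-term maximum individual exposure to
airborne hazardous releases, for exposure scientists and dispersion
modellers working with high-frequency (10–100 Hz) concentration time
series.

After a release, the health-relevant quantity downwind is the largest dose
inhalable over a short interval Δτ — the **expected maximum individual
exposure**

    D_max(Δτ) = [∫_Δτ C(t) dt]_max = C_max(Δτ) · Δτ   (µg s m⁻³),

where C_max(Δτ) is the maximum Δτ-averaged concentration. `maxexposure`
implements a deterministic peak-to-mean model of this quantity,

    D_max(Δτ) = C̄ · [ 1 + β · I · (Δτ / T_C)^(−n) ] · Δτ,

driven by three per-sensor statistics — the mean concentration C̄, the
fluctuation intensity I = var(C)/C̄², and the autocorrelation integral time
scale T_C = ∫₀^∞ R_C(τ) dτ — and two empirical parameters: a
proportionality constant β (representative value 1.5; field-refined mean
1.72) and a power-law exponent n (≈ 0.3). The package covers the full
workflow:

* **Statistics** — `summarize_series()`: moments (divisor-N), intensity,
  intermittency factor, FFT correlogram, integral time scale with
  configurable truncation, sliding-window peak concentration.
* **Model** — `predict_dmax()`, `scale_cmax()`, and closed-form inversions
  `invert_beta()` / `invert_n()` with batch screening
  (`invert_parameters()`).
* **Uncertainty** — `fit_gamma_mle()`: maximum-likelihood Gamma(shape a,
  scale b) fits of the inverted parameter populations, with 95% CIs,
  plus `gamma_summary()`, `gamma_cdf()`, `gamma_pdf_curve()`.
* **Validation** — `fac_k()` and `build_validation()`: FAC2/FAC5 metrics
  (fraction of predicted/observed pairs within a factor of 2 / 5, bounds
  inclusive).
* **Synthetic data** — `generate_series()` / `generate_campaign()`:
  seeded stationary records with controllable mean, I, T_C, intermittency;
  `generate_model_consistent_campaign()`: an exact statistics-level oracle.
* **Pipeline** — `run_full_analysis()`: batch orchestration with CSV
  outputs and a YAML run manifest; a thin CLI lives at
  `inst/scripts/run_pipeline.R`.

## Worked example

Generate a 2000-second synthetic record (0.4 s plume-like memory,
intermittent zeros), extract its statistics, and predict the worst-case
one-minute exposure:

```r
library(maxexposure)

ser <- generate_series(generator_spec(
  mean_target = 2, intensity_target = 1.5, t_c_target = 0.4,
  gamma_target = 0.2, dt = 0.01, n_samples = 2e5, seed = 42))
st <- summarize_series(ser)
st[, c("mean", "intensity", "intermittency", "t_c", "c_max", "d_max_obs")]
#>   mean intensity intermittency    t_c   c_max d_max_obs
#> 1    2    1.6845        0.2093 0.3958 52.5423    0.5254

predict_dmax(st$mean, st$intensity, st$t_c, dtau = 60,
             params = exposure_params(1.72, 0.3))
#> <exposure_prediction> dtau = 60 s: D_max = 197.085 ug s m^-3 (C_max = 3.28475 ug m^-3)
```

The record averages 2 µg m⁻³, yet the model expects some one-minute window
to average 3.28 µg m⁻³ — a 197 µg s m⁻³ dose, ~64% above the mean-based
estimate; at the 0.01 s measurement interval the observed peak is 26× the
mean. (The recovered intensity 1.68 exceeds the 1.5 target because
clipping 21% of the marginal to zero adds variance; the generator reports
this achieved value via `achieved_statistics()`.)

Closing the loop on a model-consistent campaign of 4004 sensors with
per-sensor β drawn from Gamma(2.71, 0.63):

```r
tab <- generate_model_consistent_campaign(n_sensors = 4004, seed = 1)
inv <- invert_parameters(tab, n_fixed = 0.3)
fit_gamma_mle(inv$beta)
#> <gamma_fit> maximum-likelihood Gamma(shape a, scale b)
#>   a = 2.689  [2.578, 2.8]  (95% asymptotic)
#>   b = 0.6375  [0.6085, 0.6665]
#>   mean (a*b) = 1.714, sd (b*sqrt(a)) = 1.045, n = 4004

build_validation(tab, params = exposure_params(1.72, 0.3))
#> <validation_report> predicted vs observed maximum exposure
#>   model: beta = 1.72, n = 0.3; 4004 pairs (0 dropped)
#>   FAC2 = 71.9% (2880/4004), FAC5 = 97.2% (3893/4004)
```

Inversion recovers every sampled β to machine precision; the refitted Gamma
parameters sit on the sampling truth within sampling error, and the FAC2 of
mean-parameter predictions matches its closed-form value from the Gamma CDF
(≈ 72%). See `vignettes/maximum-exposure-model.Rmd` for the model's
assumptions, the generator's construction and its fidelity limits.

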