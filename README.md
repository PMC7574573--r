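# sealforage

Analysis tools for archival biologging records from benthically foraging
marine predators. The motivating system is grey seals (*Halichoerus
grypus*) carrying time-depth-light recorders with Fastloc GPS on a
continental shelf: the tags record depth, temperature, light level and a
wet/dry flag every 10 s during dives, plus GPS fixes every 15 min at the
surface. From these records alone the package reconstructs where the
animal went, what it did, and what water it did it in — and asks whether
apparent foraging is associated with the oceanographic conditions the
animal itself measured.

The chain, each stage usable on its own:

* **tag/GPS I/O and filtering** — CSV readers/writers, removal of fixes
  with < 5 satellites or residual error > 30, and a deterministic
  10 m s⁻¹ great-circle speed filter;
* **dive processing** — rolling-window zero-offset correction, dive
  detection (dives < 5 m, > 30 min, rates ≥ 6 m s⁻¹ or 0, durations
  ≤ 20 s are discarded), and descent/bottom/ascent segmentation with the
  bottom phase defined by depths ≥ 80% of maximum depth;
* **in-situ environment** — per-dive upper-column temperature (T50, mean
  ascent temperature ≤ 50 m), light attenuation from the OLS slope of the
  log-scaled light sensor against depth (LA = −slope · ln10 / 20 m⁻¹),
  chlorophyll-*a* by inverting a configurable bio-optical model
  K_d = K_w + χ·chlaᵉ (noon-window dives ≥ 50 m only), mixed-layer depth,
  and bottom-phase means;
* **behavioural states** — a two-state hidden Markov model on the
  first-difference correlated random walk (DCRW),
  d_t | d_{t−1}, s_t ~ N₂(γ_s R(θ_s) d_{t−1}, σ_s² I), fitted by maximum
  likelihood with C++ forward/Viterbi kernels on tracks interpolated to a
  3-h step; travelling ≈ (θ ≈ 0, γ ≈ 0.9), apparent foraging ≈ (γ ≈ 0.2);
* **association models** — binomial GLMMs of foraging probability on
  water-column (chl-*a*, T50) or bottom-condition (duration, temperature,
  log depth) covariates with sex, season and two-way interactions, fitted
  by penalized quasi-likelihood with a per-seal random intercept and
  continuous-time AR(1) residual correlation, reported as odds-ratio
  tables;
* **synthetic data** — a generator for tag archives, GPS fixes and model
  datasets with known ground truth (switching DCRW tracks, trapezoidal
  benthic dives, forward-model optics, stratified temperature, haulouts,
  GPS degradation), so the whole chain is testable without animal data.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate one deployment, refit the behavioural-state model, and fit the
water-column association model on a simulated dataset:

```r
library(sealforage)
library(dplyr)

cfg <- sim_config(track_steps = 400, seed = 7)
trk <- simulate_track(cfg, seal_id = 1)
fit <- fit_hmm(as_regular_track(trk), n_restarts = 10, seed = 1)
tidy(fit)
#> # A tibble: 2 × 5
#>   state        theta gamma sigma p_stay
#>   <chr>        <dbl> <dbl> <dbl>  <dbl>
#> 1 travelling -0.0406 0.867  4.40  0.830
#> 2 foraging   -0.0842 0.210  2.03  0.878
```

The generating parameters were θ = (0, 0), γ = (0.9, 0.2),
σ = (4.4, 2.0) km: the refit recovers the directed/tortuous split and
labels the high-autocorrelation state travelling. `fit$states` holds the
Viterbi-decoded state and the posterior foraging probability per 3-h step
(`autoplot(fit)` maps them).

```r
sim <- simulate_glmm_dataset(n_seals = 12, n_obs_per_seal = 100, seed = 3)
m1 <- fit_pql_glmm(sim$observations, "water_column")
tidy(m1, exponentiate = TRUE) |> select(term, or, ci_lo, ci_hi, p.value)
#> # A tibble: 10 × 5
#>    term                 or ci_lo  ci_hi      p.value
#>  1 (Intercept)       0.416 0.101  1.71  0.254
#>  2 chl               2.54  1.54   4.19  0.000285
#>  3 T50               1.09  0.985  1.22  0.0926
#>  4 sexF              6.28  1.45  27.1   0.0361
#>  5 seasonsummer      2.19  0.513  9.38  0.290
#>  6 chl:sexF          0.582 0.367  0.924 0.0219
#>  7 chl:seasonsummer  0.265 0.163  0.430 0.0000000916
#>  8 T50:sexF          0.898 0.814  0.990 0.0311
#>  9 T50:seasonsummer  0.961 0.869  1.06  0.447
#> 10 sexF:seasonsummer 0.826 0.204  3.34  0.795
```

Rows are odds ratios with Wald 95% limits: here a 1 mg m⁻³ increase in
chlorophyll-*a* multiplies the odds of apparent foraging by ~2.5 in fall
males (the reference cell), and females forage more than males — the
qualitative structure the generating coefficients encode.
`glance(m1)` reports the CAR(1) correlation (per hour), the
random-intercept SD and the quasi-dispersion.

The full pipeline on raw records is
`read_tag_archive() |> process_dives() |> dive_environment()` for the
environment side, `read_gps_fixes() |> filter_gps() |> project_track() |>
regularize_track() |> fit_hmm()` for the movement side, and
`assemble_observations() |> fit_pql_glmm() |> odds_ratio_table()` to join
them.

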