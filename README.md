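# halotaxis

Swimming statistics and chemotaxis simulation for slow helical
microswimmers.

Halophilic archaea swim at only ~2 µm/s and reverse direction every ~15 s,
so rotational Brownian motion (directional memory time
τ\_r = 1/(2 D\_r) ≈ 6 s at D\_r ≈ 0.08 s⁻¹) randomizes their heading on the
same time scale as their own run–reverse dynamics — the opposite regime
from fast enteric bacteria, and an interesting limit for the energetics of
chemotaxis in nutrient-poor brines. halotaxis packages the full analysis
chain for this regime, for people working with 3D single-cell tracking
(e.g. holographic microscopy) or modelling motility strategies:

* **Synthetic tracks** (`generate_swimmer_track`, `generate_population`):
  helical run-and-reverse kinematics about a rotationally diffusing axis,
  Poisson reversals (optionally chemotactically biased), translational
  diffusion, 50 Hz sampling and Gaussian localization noise
  (0.4 µm lateral / 0.5 µm axial) — with the noise-free path and true
  reversal times retained as ground truth, so every downstream estimator is
  testable without experimental data.
* **Track processing** (`smooth_and_filter`, `classify_motile`,
  `reversal_statistic`, `segment_runs`, `fit_run_durations`,
  `fit_speed_distribution`): spline smoothing with a noise-matched
  discrepancy criterion, MSD-slope motility classification, reversal
  detection via the bounded statistic
  Ξ(t) = |a(t)·a(t+1)|/Δt · \[1 − v\_t/⟨v⟩\_t\], run segmentation with
  censoring of partial runs, and exponential/Gaussian fits.
* **Orientation analysis** (`direction_correlation`,
  `fit_helical_correlation`, `fit_lognormal`): the helical-plus-Brownian
  direction-correlation model
  C(τ) = e^(−2 D\_r τ)\[cos²θ + sin²θ cos(ωτ)\],
  which separates body-helix oscillation from true rotational diffusion
  (the pure-exponential fit overestimates D\_r on helical tracks).
* **Sector chemotaxis assay** (`classify_run_direction`, `sector_summary`,
  `fractional_drift`): mean run durations up/perpendicular/down a gradient
  and the projection-corrected drift estimate
  v\_x/v₀ = (1/3)·2(T⁺−T⁻)/(T⁺+T⁻).
* **Brownian dynamics simulator** (`sim_config`, `simulate_ensemble`,
  `sweep_tau_run`, `sweep_speed`): prolate-ellipsoid swimmers (Perrin
  friction, `perrin_friction`) with run-reverse or run-tumble
  reorientation whose rate λ(t) = λ\[1 − ∫c(t′)R(t−t′)dt′\] responds to the
  concentration history through the adaptive kernel
  R(t) = W k e^(−kt)\[1 − kt/2 − (kt/2)²\] (∫R dt = 0: perfect adaptation),
  reporting drift velocity, MSD along the gradient and the chemotactic
  efficiency ε = v\_x/(γ v₀²).

The compiled stepping core makes ensembles of 10⁴-second trajectories a
matter of seconds. All randomness is seeded; identical configurations give
bit-identical results. The methods vignette
(`vignettes/halotaxis-methods.Rmd`) documents the models, parameter
defaults and design decisions.

## Worked example

```r
library(halotaxis)

# 1. synthesize a population of slow helical run-and-reverse swimmers
cfg <- generator_config(v0 = 2, tau_run = 14.7, D_r = 0.08,
                        duration = 90, frame_rate = 50)
tracks <- generate_population(cfg, n_cells = 30, seed = 42)

# 2. smooth, segment into runs, and fit the motility statistics
smoothed <- process_tracks(tracks)
runs <- segment_all_runs(smoothed)
fit_run_durations(runs$duration_s[!runs$censored])
#> <run_duration_fit: tau_run = 13.6 +/- 1.2 s (n = 139)>
fit_speed_distribution(pooled_speeds(smoothed))
#> <speed_fit: 1.9 +/- 0.482 um/s (mean +/- s.d., n = 135000)>
```

The fitted mean run duration (13.6 ± 1.2 s) and speed (1.90 µm/s) recover
the generating values (14.7 s, 2 µm/s after smoothing losses) from the
noisy tracks alone.

```r
# 3. per-track rotational diffusivity from the helical correlation model
ocfg <- generator_config(v0 = 2, tau_run = Inf, D_r = 0.08, D_t = 0,
                         theta = 0.3, omega = 3, noise_lateral = 0,
                         noise_axial = 0, duration = 150)
fits <- fit_orientation_population(generate_population(ocfg, 30, seed = 5),
                                   max_lag = 10)
head(fits, 3)
#>   track_id        D_r    omega     theta    tau_r         rms
#> 1 cell_001 0.10083155 3.044971 0.2760159 4.958766 0.021021305
#> 2 cell_002 0.06285806 2.969065 0.3103016 7.954429 0.009433788
#> 3 cell_003 0.07418226 3.024382 0.2975330 6.740156 0.015966979
fit_lognormal(fits$D_r)
#> <lognormal_fit: meanlog = -2.53, sdlog = 0.17, mode = 0.0775 (n = 30)>
```

The population's modal D\_r (0.0775 s⁻¹) recovers the generating
0.08 s⁻¹; per-track ω and θ land on the generating 3 rad/s and 0.3 rad.

```r
# 4. fractional chemotactic drift from sector run durations
fractional_drift(20.7, 14.6)   # T+ and T- in seconds
#> [1] 0.115203

# 5. Brownian dynamics: bipolar chemotaxis at archaeal parameters
sim <- sim_config(mode = "bipolar", n_cells = 50, duration = 2000, seed = 1)
simulate_ensemble(sim)
#> <ensemble_result: 50 cells x 2e+03 s, mode = bipolar>
#>   v = (0.09717, 0.01208, -0.005459) um/s;  v_x/v0 = 0.04858 +/- 0.0055
#>   reversals/cell = 130.7;  floored fraction = 2.3e-05
```

Step 4 turns the up/down-gradient mean run durations 20.7 s and 14.6 s into
a fractional drift speed of 0.115 (dimensionless, ~11% of the swimming
speed). Step 5 simulates 50 bipolar-responding cells in a linear gradient:
they drift up-gradient at v\_x ≈ 0.097 µm/s (≈ 5% of v₀) while the y and z
components stay at noise level, and the calibrated sensitivity almost never
drives the reversal rate to its floor.

A whole generate → process → orientation → assay chain, with every fitted
quantity in one JSON report, is available as `run_pipeline()`; see
`?run_pipeline` for the config layout.

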