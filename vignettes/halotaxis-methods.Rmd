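---
title: "Models and methods behind halotaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind halotaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

halotaxis analyses the swimming statistics and chemotactic performance of
slow, run-and-reverse microswimmers — halophilic archaea are the motivating
system, swimming at ~2 µm/s with mean run durations above ten seconds, so
that rotational Brownian motion and intrinsic reorientation act on similar
time scales. This vignette records the models the package implements, the
choices made where the design was genuinely open, and what the synthetic
data generator does and does not emulate.

## The swimmer model

A cell is described by a unit orientation `a(t)` along which it swims at
fixed speed `v0`, subject to three stochastic influences:

* **Rotational diffusion.** Per step of length `dt`, the orientation is
  rotated by independent Gaussian angles of variance `2 D_r dt` about two
  perpendicular transverse axes and renormalized — the standard small-step
  isotropic scheme. The directional memory time is `tau_r = 1/(2 D_r)`:
  `D_r = 0.08 1/s` gives `tau_r ≈ 6.2 s`.
* **Reversals.** Reorientation events arrive as a Poisson process at rate
  `lambda = 1/tau_run` and flip the orientation exactly (run-and-reverse). A
  run-and-tumble variant instead rotates the orientation by a
  gamma-distributed angle (shape 4, mean 68°, capped at 180°, azimuth
  uniform) — the classic enteric-bacterium turning statistics, used by the
  fast-swimmer preset (`v0 = 20 µm/s`, `tau_run = 1 s`, lengthen-only).
* **Translational diffusion.** Gaussian displacements per axis; components
  parallel and perpendicular to the orientation are derived from the Perrin
  friction factors of a prolate spheroid (default semi-axes 2.25 × 0.35 µm: the
  cell body's width, but about three times its length, because the
  flagellar bundle lengthens the effective hydrodynamic ellipsoid; medium
  viscosity 1.82 mPa s, 298 K), or a single isotropic
  `D_t` can be given directly.

### Helical kinematics (generator only)

Real cell bodies wobble: the tracked point follows a small helix about the
swimming axis. The generator represents this with a helix axis vector `h(t)`
(the object that diffuses rotationally and flips at reversals) plus a phase
advancing at angular frequency `omega`; the tangent makes the fixed pitch
angle `theta` with the axis. In the noiseless, non-diffusing limit the
direction correlation of such a track is exactly
`cos²(theta) + sin²(theta) cos(omega tau)`. The helix radius is implied,
`r = v0 sin(theta)/omega` (≈ 0.2 µm at the defaults `theta = 0.3`,
`omega = 3 rad/s` — a "small-amplitude" wobble comparable to the
localization noise, with a period of ~2 s; the defaults are chosen once as
plausible values for these cells, the analysis never assumes them).
Reversals flip `h` and one transverse frame vector so that handedness is
preserved. Because rotations are linear maps, pre-computing the diffusing
frame and applying the reversal sign afterwards is exact, which is how the
generator vectorizes the unbiased case.

### Direction correlation and the helical fit

For rotational diffusivity estimation the package computes
`C(tau) = <a(t)·a(t+tau)>` within runs only (pairs straddling a reversal,
or within 1 s of one, are excluded) and fits

```
C(tau) = exp(-2 D_r tau) [cos²(theta) + sin²(theta) cos(omega tau)]
```

by weighted least squares. Fitting the pure-Brownian form
`exp(-2 D_r tau)` to helical data overestimates `D_r` — the package asserts
this property in its tests, and offers both models. Numerical choices: the
oscillation frequency is multi-started over 8 log-spaced values between one
cycle per curve length and the Nyquist rate (the frequency is not known a
priori and the residual surface has local minima in `omega`); bounds are
`D_r ≥ 0`, `0 ≤ theta ≤ π/2`; the nested `theta = 0` (pure-exponential)
solution is always evaluated as a candidate so the model reduces exactly
when the oscillation is absent. The lag grid is dense (every frame) up to
2 s and logarithmic beyond, to resolve the oscillation while bounding cost.
Per-track `D_r` estimates are right-skewed and summarized by the mode of a
log-normal fit.

## Track processing

Raw tracks are smoothed with cubic smoothing splines per coordinate, after
linear interpolation of gaps up to 5 frames (longer gaps split the track)
and rejection of segments shorter than 3 s. The smoothing strength is set by
a discrepancy principle: the heaviest smoothing whose RMS residual does not
exceed `1.1 ×` the localization noise (0.4 µm lateral, 0.5 µm axial by
default). The 1.1 factor is calibrated on synthetic ground truth: matching
the residual to the noise exactly leaves correlated wiggle in the fitted
curve that inflates finite-difference speeds noticeably at 50 Hz, while the
inflated target gives unbiased speeds and still tracks the true path well
inside the noise level. If even maximal smoothing leaves the residual below the
target, the track has no resolvable noise and is returned unsmoothed.
Swimmers are separated from diffusers by the log–log MSD slope on lags
0.1–2 s (threshold 1.5, between the diffusive slope 1 and ballistic 2).

### Reversal detection

The per-frame statistic

```
Xi(t) = |a(t)·a(t+1)| / dt * [1 - v_t / <v>_t]
```

peaks where the cell slows while its successive tangents stay aligned, i.e.
at the V-shaped kinks that reversals produce in a smoothed slow track. As
printed, the first factor is ≈ 1/dt both during runs and at reversals, so
discrimination rests on the speed dip; a variant replacing it with the
angular speed `arccos(a·a')/dt` is available. `Xi` is bounded by `1/dt`,
and its speed bracket is normalized by the track-mean speed, so the default
event threshold is the scale-invariant `0.5/dt` — an event is a local
maximum where the speed dips below half the track mean. (A threshold
proportional to the median of `Xi` was considered and rejected: baseline
speed fluctuations put any such multiple near or above the hard ceiling
`1/dt`, where real reversal peaks live.) Events closer than 1 s are merged,
keeping the larger peak. Runs are the intervals between events; the leading
and trailing intervals are censored (their bounding reversal was not
observed) and are excluded from duration fits, where they would bias the
exponential mean downward. On synthetic ground truth this pipeline recovers the
generating mean run duration within three standard errors, and localizes
programmed reversals within two frames at low noise and within half a
second at the full 0.4 µm noise level.

Run durations are fit by the exponential maximum likelihood estimator (the
sample mean, s.e. `mean/sqrt(n)`); pooled smoothed speeds by a Gaussian
(sample mean and s.d.).

## The chemotaxis model

The reorientation rate responds linearly to the concentration history:

```
lambda(t) = lambda [1 - ∫ c(t') R(t - t') dt'],
R(t) = W k exp(-k t) [1 - k t/2 - (k t/2)²]
```

with memory rate `k = 0.5 1/s` (a 2 s memory) decoupled from `lambda`. The
kernel integrates to zero, so a constant concentration never biases the
rate (perfect adaptation); a sustained ramp of slope `g` settles at
`lambda (1 - 3 W g / (2k))`. Response modes restrict the sign of the
modulation: run-lengthening only lets the rate fall below `lambda`,
run-shortening only rise, bipolar allows both; the rate is floored at zero
and flooring is counted (it indicates receptor saturation).

The convolution is evaluated with three exponentially decaying moment
accumulators (for the `e^{-kt}`, `t e^{-kt}`, `t² e^{-kt}` components),
updated recursively and exactly for piecewise-constant concentration —
O(1) per step, validated against brute-force quadrature. The memory is
pre-filled with the steady-state moments of the starting concentration so
trajectories begin fully adapted, with no startup transient from the
convolution's lower limit.

**Sensitivity calibration.** `W` is chosen so that a cell swimming straight
up the gradient at a reference speed experiences a steady-state modulation
`beta`; the default `beta = 0.9` is the largest modulation that never drives
the rate to its floor. In speed sweeps the reference speed is held at the
archaeal 2 µm/s so that a single organism (one `W`) is swept across speeds:
re-calibrating at every speed would make the dynamics scale-free in `v0`
(drift depends on speed only through the modulation depth
`3 W v0 |∇c|/(2k)`) and the fractional drift exactly flat. A consequence,
verified by the package's own sweeps, is that the fractional drift of this
model rises with modulation depth without a sharp plateau (run-shortening
down-gradient keeps gaining even deep into flooring), so the speed at which
it stops gaining materially lands at the top of the swept range rather than
at 2 µm/s; the optimal-run-duration structure, by contrast, is robust:
bipolar drift peaks at `tau_run ≈ 10 s ≈ 1.6 tau_r`, and run-shortening
strategies prefer longer unstimulated runs than run-lengthening ones,
though the one-sided optima are shallow and their grid locations
statistically marginal at the ensemble sizes used here.

**Simulation loop.** Per step: update the concentration memory, evaluate
`lambda(t)`, reorient with probability `lambda(t) dt` (a validity check
requires `lambda dt < 0.1` at configuration and errors above 1), rotate the
orientation diffusively, translate (`v0 dt` plus anisotropic diffusion).
Defaults follow the study conditions: `dt = 0.033 s`, 100 cells, 10⁴ s,
linear gradient `c(x) = x`, and 60 s of orientation-only pre-equilibration
at zero chemotactic bias. Drift velocity is the through-origin straight-line
fit of the ensemble mean position; its error bars are the s.e.m. of
per-cell slopes (the residual-based s.e. of the mean series is meaningless
because those residuals are a correlated random walk). The MSD along the
gradient is lag-averaged for unbiased ensembles and measured from the
trajectory origin for chemotactic ones, whose statistics are not
stationary. Chemotactic efficiency is `epsilon = v_x/(gamma v0²)` with
`gamma` the orientation-averaged Perrin friction; the friction-scaled
`epsilon gamma = v_x/v0²` compares swimmers of identical geometry.

## The sector assay

Runs are classified by the cosine between their net displacement direction
and the gradient: within 60° cones (`|cos| ≥ 0.5`) about the poles they are
"up" or "down", else perpendicular — the perpendicular sector is the
built-in control. The fractional drift estimate is

```
v_x / v0 = P · 2 (T⁺ - T⁻) / (T⁺ + T⁻)
```

with projection factor `P = 1/3` by default: the literal one-dimensional
formula (`P = 1`) overstates sector-table drift estimates about threefold,
while `P = 1/3` reproduces published sector tables within their stated
uncertainties (the package verifies both statements). On uncensored
simulator runs the sector estimate still overshoots the direct drift
severalfold (the cross-module test bounds it within a factor of four); we
attribute the difference to experimental truncation of the longest
(preferentially up-gradient) runs by the field of view, which the
estimator's calibration absorbs. Sector s.e.m.s are
propagated to the drift estimate to first order.

## What the generator does and does not emulate

It reproduces: helical run-and-reverse kinematics with rotational diffusion
of the helix axis; exponential run durations, optionally biased by the same
linear-response rate as the simulator; 50 Hz sampling; i.i.d. Gaussian
localization noise (0.4 µm lateral, 0.5 µm axial); frame drop-outs only via
user-constructed gaps. It does not emulate: correlated or
intensity-dependent localization errors, track fragmentation and linking
mistakes, boundary effects (walls, field-of-view truncation of long runs),
cell-to-cell parameter spread (each track shares the configured
parameters), speed fluctuations along a run, or chemokinesis. Pipeline
tests passing on generated data therefore validate the estimators under
the model's own assumptions — they do not certify robustness to those
real-data artefacts, of which field-of-view truncation is the one we know
to matter (see the sector assay above).

## Problem sizes and numerical details

Test and reproduction runs are scaled to desk hardware as the package's own
choice of study size: sweeps use 50 cells × 3000 s per parameter point;
property checks use 80–400 cells and 10–10⁴ s as noted in the tests;
end-to-end pipeline checks use 25–50 tracks of 60–150 s at 50 Hz. The
integration step is fixed at the sampling interval (generator) or 0.033 s
(simulator); halving it changes ensemble drift by well under 5%.
Degenerate inputs fail loudly: zero-variance speed samples, zero mean
speeds, non-monotone timestamps, empty sectors (drift reported as
undefined with a warning), `D_r ≤ 0` relaxation times, and invalid
rate discretizations are all errors or flagged results, not silent
defaults. All randomness flows from user-supplied integer seeds;
identical configurations and seeds give bit-identical tracks, ensembles
and pipeline reports.
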