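#' Configuration for the Brownian dynamics chemotaxis simulator
#'
#' Cells are prolate-ellipsoid swimmers moving at fixed speed along their
#' orientation vector, which undergoes rotational diffusion; reorientations
#' (exact reversals or run-and-tumble turns) arrive at the adaptive
#' linear-response rate of [tumble_rate()] evaluated on the concentration
#' history in a linear gradient `c(r) = gradient . r`. Defaults are the
#' archaeal parameters: `v0 = 2` um/s, `tau_run = 14.7` s, `D_r = 0.08` 1/s,
#' reverse-only, `dt = 0.033` s, 100 cells, 1e4 s, 60 s orientation
#' equilibration.
#'
#' Translational diffusivities are derived from the Perrin factors of the
#' configured ellipsoid (anisotropic: parallel and perpendicular components)
#' unless `D_t` is given, in which case diffusion is isotropic at `D_t`.
#'
#' The chemotactic sensitivity `W` defaults to [calibrate_sensitivity()] at
#' the reference speed `sensitivity_speed` (by default `v0` itself). When
#' sweeping `v0`, fix `sensitivity_speed` so that `W` describes one organism
#' across the sweep; re-calibrating at every speed would make the response
#' scale-free in `v0` and suppress the saturation the model exhibits.
#'
#' @param v0 swimming speed (um/s).
#' @param tau_run unstimulated mean run duration (s); `Inf` disables
#'   reorientation.
#' @param D_r rotational diffusivity (1/s).
#' @param D_t isotropic translational diffusivity (um^2/s), or `NULL` to
#'   derive anisotropic components from `semi_axes`/`viscosity`/`temperature`.
#' @param semi_axes ellipsoid semi-axes c(a, b) (um) for friction.
#' @param viscosity medium viscosity (mPa s).
#' @param temperature temperature (K).
#' @param dt integration step (s); `dt / tau_run` must stay below 0.1.
#' @param duration simulated time (s).
#' @param n_cells ensemble size.
#' @param gradient gradient vector of the linear concentration field.
#' @param reorientation `"reverse"` (exact flip) or `"tumble"`.
#' @param tumble_mean_angle,tumble_shape gamma-distributed tumble angle:
#'   mean (rad) and shape (classic run-and-tumble statistics, mean 68 deg).
#' @param mode chemotactic mode: `"none"`, `"lengthen"`, `"shorten"`,
#'   `"bipolar"`.
#' @param memory_rate kernel rate constant k (1/s); memory length 1/k.
#' @param sensitivity sensitivity W, or `NULL` to calibrate.
#' @param beta calibration target modulation (see [calibrate_sensitivity()]).
#' @param sensitivity_speed reference speed (um/s) for calibration;
#'   default `v0`.
#' @param equilibration orientation pre-equilibration time (s).
#' @param record_dt interval (s) between recorded positions; defaults to
#'   about 1 s (coarse recording keeps long ensembles small).
#' @param store_directions,store_reversals also record orientation vectors /
#'   reorientation event times.
#' @param seed integer seed; ensembles are bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(v0 = 2, tau_run = 14.7, D_r = 0.08, D_t = NULL,
                       semi_axes = c(2.25, 0.35), viscosity = 1.82,
                       temperature = 298,
                       dt = 0.033, duration = 1e4, n_cells = 100,
                       gradient = c(1, 0, 0),
                       reorientation = c("reverse", "tumble"),
                       tumble_mean_angle = 68 * pi / 180, tumble_shape = 4,
                       mode = c("none", "lengthen", "shorten", "bipolar"),
                       memory_rate = 0.5, sensitivity = NULL, beta = 0.9,
                       sensitivity_speed = NULL,
                       equilibration = 60, record_dt = NULL,
                       store_directions = FALSE, store_reversals = FALSE,
                       seed = 1L) {
  reorientation <- match.arg(reorientation)
  mode <- match.arg(mode)
  if (!(dt > 0)) stop("dt must be positive")
  if (!(duration > dt)) stop("duration must exceed dt")
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (!(tau_run > 0)) stop("tau_run must be positive")
  lambda0 <- if (is.finite(tau_run)) 1 / tau_run else 0
  if (lambda0 * dt >= 0.1)
    stop("dt / tau_run must be below 0.1 for a valid rate discretization")
  if (is.null(D_t)) {
    fr <- perrin_friction(semi_axes[1], semi_axes[2], viscosity, temperature)
    D_par <- fr$D_par; D_perp <- fr$D_perp; gamma_avg <- fr$gamma_avg
  } else {
    D_par <- D_perp <- D_t
    gamma_avg <- perrin_friction(semi_axes[1], semi_axes[2], viscosity,
                                 temperature)$gamma_avg
  }
  gmag <- sqrt(sum(gradient^2))
  if (mode != "none" && gmag == 0) stop("chemotaxis needs a nonzero gradient")
  if (is.null(sensitivity)) {
    sensitivity <- if (mode == "none") 0
    else calibrate_sensitivity(
      if (is.null(sensitivity_speed)) v0 else sensitivity_speed,
      gmag, memory_rate, beta)
  }
  if (is.null(record_dt)) record_dt <- max(dt, round(1 / dt) * dt)
  structure(list(
    v0 = v0, tau_run = tau_run, lambda0 = lambda0, D_r = D_r,
    D_par = D_par, D_perp = D_perp, gamma_avg = gamma_avg,
    semi_axes = semi_axes, viscosity = viscosity, temperature = temperature,
    dt = dt, duration = duration, n_cells = as.integer(n_cells),
    gradient = gradient, reorientation = reorientation,
    tumble_mean_angle = tumble_mean_angle, tumble_shape = tumble_shape,
    mode = mode, memory_rate = memory_rate, sensitivity = sensitivity,
    beta = beta, equilibration = equilibration, record_dt = record_dt,
    store_directions = store_directions, store_reversals = store_reversals,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config: %d cells x %.3g s, dt = %.3g s, v0 = %.3g um/s, ",
           "tau_run = %.3g s, D_r = %.3g 1/s, %s, mode = %s>\n"),
    x$n_cells, x$duration, x$dt, x$v0, x$tau_run, x$D_r,
    x$reorientation, x$mode))
  invisible(x)
}

#' Run a Brownian dynamics ensemble
#'
#' Integrates `n_cells` independent swimmers under the configuration and
#' returns the ensemble result: recorded positions, the ensemble mean
#' position, the drift velocity from a through-origin straight-line fit
#' ([drift_velocity()]), the fractional drift along the gradient, and the
#' chemotactic efficiency.
#'
#' @param config a [sim_config()].
#' @return A list of class `ensemble_result` with elements `config`, `times`,
#'   `positions` (array: time x axis x cell), `r_avg`, `drift` (velocity
#'   vector and s.e.), `fractional_drift`, `efficiency`, `n_reversals`,
#'   `reversal_times` (if stored), `directions` (if stored),
#'   `floored_fraction`, `max_lambda_dt`.
#' @export
simulate_ensemble <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_steps <- round(config$duration / config$dt)
  record_every <- max(1L, round(config$record_dt / config$dt))
  raw <- simulate_ensemble_cpp(
    n_cells = config$n_cells, n_steps = n_steps, dt = config$dt,
    v0 = config$v0, lambda0 = config$lambda0, Dr = config$D_r,
    Dpar = config$D_par, Dperp = config$D_perp,
    grad = as.numeric(config$gradient), W = config$sensitivity,
    k = config$memory_rate,
    mode = match(config$mode, c("none", "lengthen", "shorten", "bipolar")) - 1L,
    reorient = match(config$reorientation, c("reverse", "tumble")) - 1L,
    tumble_shape = config$tumble_shape,
    tumble_scale = config$tumble_mean_angle / config$tumble_shape,
    equil_steps = round(config$equilibration / config$dt),
    record_every = record_every,
    store_directions = config$store_directions,
    store_reversals = config$store_reversals)

  r_avg <- apply(raw$positions, c(1, 2), mean)
  colnames(r_avg) <- c("x", "y", "z")
  drift <- drift_velocity(raw$times, r_avg)
  # honest errors: s.e.m. of per-cell through-origin slopes (the residuals of
  # the mean series are a correlated random walk, so its fit s.e. is useless)
  keep <- raw$times > 0
  st2 <- sum(raw$times[keep]^2)
  cell_v <- apply(raw$positions[keep, , , drop = FALSE], c(2, 3),
                  function(x) sum(x * raw$times[keep])) / st2
  drift$se <- apply(cell_v, 1, sd) / sqrt(config$n_cells)
  drift$v_cells <- cell_v
  gmag <- sqrt(sum(config$gradient^2))
  ghat <- if (gmag > 0) config$gradient / gmag else c(1, 0, 0)
  v_x <- sum(drift$v * ghat)
  eff <- if (config$v0 > 0)
    chemotactic_efficiency(v_x, config$v0, config$gamma_avg)
  else list(epsilon = NA_real_, epsilon_gamma = NA_real_)
  structure(list(
    config = config, times = raw$times, positions = raw$positions,
    directions = if (config$store_directions) raw$directions,
    reversal_times = if (config$store_reversals) raw$reversal_times,
    n_reversals = raw$n_reversals,
    r_avg = r_avg, drift = drift, v_x = v_x,
    fractional_drift = if (config$v0 > 0) v_x / config$v0 else NA_real_,
    efficiency = eff,
    floored_fraction = raw$floored_fraction,
    max_lambda_dt = raw$max_lambda_dt), class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result: %d cells x %.3g s, mode = %s>\n",
              x$config$n_cells, x$config$duration, x$config$mode))
  cat(sprintf("  v = (%.4g, %.4g, %.4g) um/s;  v_x/v0 = %.4g +/- %.2g\n",
              x$drift$v[1], x$drift$v[2], x$drift$v[3],
              x$fractional_drift,
              x$drift$se[1] / max(x$config$v0, .Machine$double.eps)))
  cat(sprintf("  reversals/cell = %.1f;  floored fraction = %.2g\n",
              mean(x$n_reversals), x$floored_fraction))
  invisible(x)
}

#' Drift velocity from an ensemble mean-position series
#'
#' Component-wise least-squares slope of `r_avg(t) = v t` constrained through
#' the origin, with standard errors from the fit residuals.
#'
#' @param times time points (s), at least 10.
#' @param r_avg matrix of mean positions (rows matching `times`, columns
#'   x,y,z) or a vector for a single component.
#' @return A list with `v` (um/s, per component) and `se`.
#' @export
drift_velocity <- function(times, r_avg) {
  r_avg <- as.matrix(r_avg)
  keep <- times > 0
  if (sum(keep) < 10) stop("need at least 10 nonzero time points")
  tt <- times[keep]
  st2 <- sum(tt^2)
  v <- colSums(r_avg[keep, , drop = FALSE] * tt) / st2
  res <- r_avg[keep, , drop = FALSE] - outer(tt, v)
  se <- sqrt(colSums(res^2) / (length(tt) - 1) / st2)
  list(v = unname(v), se = unname(se))
}

#' Mean-squared displacement along the gradient
#'
#' For non-chemotactic (stationary) ensembles the MSD is lag-averaged over
#' each trajectory; for chemotactic ensembles stationarity is broken by the
#' gradient, so the displacement is measured from the trajectory origin
#' (`<x(t)^2>` vs `t`). Returned as `<x^2(tau)>/tau` with the local log-log
#' exponent `alpha` of that ratio.
#'
#' @param result an [simulate_ensemble()] result.
#' @param from_origin measure from the trajectory start; defaults to `TRUE`
#'   for chemotactic modes.
#' @param n_lags number of logarithmically spaced lags.
#' @return data.frame with `tau`, `msd`, `msd_over_tau`, `alpha`.
#' @export
msd_along_gradient <- function(result, from_origin = NULL, n_lags = 30) {
  cfg <- result$config
  if (is.null(from_origin)) from_origin <- cfg$mode != "none"
  gmag <- sqrt(sum(cfg$gradient^2))
  ghat <- if (gmag > 0) cfg$gradient / gmag else c(1, 0, 0)
  # per-cell displacement component along the gradient
  x <- result$positions[, 1, ] * ghat[1] + result$positions[, 2, ] * ghat[2] +
    result$positions[, 3, ] * ghat[3]
  x <- as.matrix(x)
  times <- result$times
  nt <- length(times)
  idx <- unique(round(exp(seq(log(2), log(nt), length.out = n_lags))))
  idx <- idx[idx >= 2 & idx <= nt]
  if (from_origin) {
    tau <- times[idx]
    msd <- vapply(idx, function(i) mean((x[i, ] - x[1, ])^2), numeric(1))
  } else {
    tau <- times[idx] - times[1]
    msd <- vapply(idx, function(i) {
      L <- i - 1
      d <- x[(1 + L):nt, , drop = FALSE] - x[1:(nt - L), , drop = FALSE]
      mean(d^2)
    }, numeric(1))
  }
  ratio <- msd / tau
  alpha <- c(NA_real_, diff(log(ratio)) / diff(log(tau)))
  data.frame(tau = tau, msd = msd, msd_over_tau = ratio, alpha = alpha)
}

#' Chemotactic efficiency
#'
#' Drift speed per unit propulsive power: `epsilon = v_x / P` with
#' `P = gamma v0^2` the power dissipated against hydrodynamic friction at
#' speed `v0`. Also returns the friction-scaled `epsilon * gamma = v_x/v0^2`
#' used to compare swimmers of identical geometry.
#'
#' @param v_x drift speed up the gradient (um/s).
#' @param v0 swimming speed (um/s), > 0.
#' @param gamma friction coefficient (pN s / um), > 0.
#' @return A list with `power` (pN um / s), `epsilon`, `epsilon_gamma`.
#' @export
chemotactic_efficiency <- function(v_x, v0, gamma) {
  if (!(v0 > 0)) stop("v0 must be positive")
  if (!(gamma > 0)) stop("gamma must be positive")
  P <- gamma * v0^2
  list(power = P, epsilon = v_x / P, epsilon_gamma = v_x / v0^2)
}

#' Sweep the unstimulated run duration
#'
#' Runs one ensemble per `tau_run` value and chemotactic mode and collects
#' the fractional drift speeds; used to locate the run duration that
#' maximizes chemotactic drift.
#'
#' @param tau_values run durations to sweep (s).
#' @param modes chemotactic modes to include.
#' @param seed master seed (per-ensemble seeds derived from it).
#' @param ... overrides passed to [sim_config()] (e.g. `n_cells`,
#'   `duration`).
#' @return data.frame with `mode`, `tau_run`, `fractional_drift`, `se`.
#' @export
sweep_tau_run <- function(tau_values = c(2, 5, 10, 20, 40),
                          modes = c("bipolar", "lengthen", "shorten"),
                          seed = 1L, ...) {
  seeds <- derive_seeds(seed, length(tau_values) * length(modes))
  rows <- list()
  i <- 0L
  for (mode in modes) for (tau in tau_values) {
    i <- i + 1L
    cfg <- sim_config(tau_run = tau, mode = mode, seed = seeds[i], ...)
    res <- simulate_ensemble(cfg)
    rows[[i]] <- data.frame(mode = mode, tau_run = tau,
                            fractional_drift = res$fractional_drift,
                            se = res$drift$se[1] / cfg$v0)
  }
  do.call(rbind, rows)
}

#' Sweep the swimming speed
#'
#' Runs one ensemble per speed at a fixed sensitivity (calibrated once at
#' `sensitivity_speed`) and collects fractional drift and friction-scaled
#' efficiency.
#'
#' @param v0_values speeds to sweep (um/s).
#' @param sensitivity_speed reference speed (um/s) at which W is calibrated.
#' @param mode chemotactic mode.
#' @param seed master seed.
#' @param ... overrides passed to [sim_config()].
#' @return data.frame with `v0`, `fractional_drift`, `se`, `epsilon_gamma`.
#' @export
sweep_speed <- function(v0_values = c(0.5, 1, 2, 4, 8),
                        sensitivity_speed = 2, mode = "bipolar",
                        seed = 1L, ...) {
  seeds <- derive_seeds(seed, length(v0_values))
  rows <- lapply(seq_along(v0_values), function(i) {
    cfg <- sim_config(v0 = v0_values[i], mode = mode,
                      sensitivity_speed = sensitivity_speed,
                      seed = seeds[i], ...)
    res <- simulate_ensemble(cfg)
    data.frame(v0 = v0_values[i], fractional_drift = res$fractional_drift,
               se = res$drift$se[1] / cfg$v0,
               epsilon_gamma = res$efficiency$epsilon_gamma)
  })
  do.call(rbind, rows)
}

#' Build a run table from simulator reversal events
#'
#' Converts the recorded positions and stored reversal times of one simulated
#' cell into runs (direction and duration between consecutive reversals), the
#' ground-truth analogue of [segment_runs()] for simulator output.
#'
#' @param result an [simulate_ensemble()] result with
#'   `store_reversals = TRUE`.
#' @return A `run_table` across all cells (first/last runs censored).
#' @export
runs_from_reversals <- function(result) {
  if (is.null(result$reversal_times))
    stop("simulate with store_reversals = TRUE")
  times <- result$times
  rows <- list()
  for (cell in seq_len(result$config$n_cells)) {
    ev <- result$reversal_times[[cell]]
    bounds <- c(times[1], ev, times[length(times)])
    pos <- result$positions[, , cell]
    for (r in seq_len(length(bounds) - 1L)) {
      i0 <- which.min(abs(times - bounds[r]))
      i1 <- which.min(abs(times - bounds[r + 1]))
      if (i1 <= i0) next
      d <- pos[i1, ] - pos[i0, ]
      nd <- sqrt(sum(d^2))
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = sprintf("sim_%03d", cell),
        start_s = bounds[r], end_s = bounds[r + 1],
        duration_s = bounds[r + 1] - bounds[r],
        censored = (r == 1L || r == length(bounds) - 1L),
        dir_x = if (nd > 0) d[1] / nd else NA_real_,
        dir_y = if (nd > 0) d[2] / nd else NA_real_,
        dir_z = if (nd > 0) d[3] / nd else NA_real_,
        mean_speed = nd / (times[i1] - times[i0]))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("run_table", "data.frame")
  res
}
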