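#' Configuration for the synthetic track generator
#'
#' Defines the statistical structure of a generated 3D trajectory: helical
#' run-and-reverse swimming about a slowly diffusing helix axis, Poisson
#' reversals, translational Brownian motion, and per-frame Gaussian
#' localization noise. Defaults emulate the slow halophilic archaea that
#' motivate the package: 2 um/s swimming, 14.7 s mean runs, rotational
#' diffusivity 0.08 1/s, 50 Hz sampling, 0.4 um lateral / 0.5 um axial
#' localization noise.
#'
#' The helix is parameterized by the pitch angle `theta` (angle between the
#' instantaneous tangent and the helix axis) and angular frequency `omega`;
#' the implied helix radius is `v0 * sin(theta) / omega`. With the defaults
#' (theta = 0.3 rad, omega = 3 rad/s) the radius is ~0.2 um, a small-amplitude
#' wobble comparable to the localization noise.
#'
#' @param v0 swimming speed along the track tangent (um/s).
#' @param tau_run mean run duration (s); `Inf` disables reversals.
#' @param D_r rotational diffusivity of the helix axis (1/s).
#' @param D_t translational diffusivity (um^2/s, isotropic). `NULL` derives
#'   the orientation-averaged value from [perrin_friction()] with `semi_axes`
#'   and `viscosity`.
#' @param theta helix pitch angle (rad), in `[0, pi/2)`.
#' @param omega helix angular frequency (rad/s).
#' @param frame_rate sampling rate (Hz).
#' @param noise_lateral,noise_axial localization noise s.d. (um) in x,y and z.
#' @param duration track duration (s).
#' @param seed integer seed; identical (config, seed) pairs generate
#'   bit-identical tracks.
#' @param semi_axes,viscosity,temperature used only to derive `D_t` when it is
#'   `NULL`; the default semi-axes describe the effective hydrodynamic
#'   ellipsoid of a flagellated cell (roughly three times the body length).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(v0 = 2, tau_run = 14.7, D_r = 0.08, D_t = NULL,
                             theta = 0.3, omega = 3, frame_rate = 50,
                             noise_lateral = 0.4, noise_axial = 0.5,
                             duration = 60, seed = 1L,
                             semi_axes = c(2.25, 0.35), viscosity = 1.82,
                             temperature = 298) {
  if (v0 < 0) stop("v0 must be >= 0")
  if (!(tau_run > 0)) stop("tau_run must be positive")
  if (D_r < 0) stop("D_r must be >= 0")
  if (theta < 0 || theta >= pi / 2) stop("theta must lie in [0, pi/2)")
  if (omega < 0) stop("omega must be >= 0")
  if (!(frame_rate > 0)) stop("frame_rate must be positive")
  if (noise_lateral < 0 || noise_axial < 0) stop("noise s.d. must be >= 0")
  if (is.null(D_t))
    D_t <- perrin_friction(semi_axes[1], semi_axes[2], viscosity,
                           temperature)$D_avg
  if (D_t < 0) stop("D_t must be >= 0")
  structure(list(v0 = v0, tau_run = tau_run, D_r = D_r, D_t = D_t,
                 theta = theta, omega = omega, frame_rate = frame_rate,
                 noise_lateral = noise_lateral, noise_axial = noise_axial,
                 duration = duration, seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    paste0("<generator_config: v0 = %.2g um/s, tau_run = %.3g s, ",
           "D_r = %.3g 1/s, %g Hz, %.3g s>\n"),
    x$v0, x$tau_run, x$D_r, x$frame_rate, x$duration))
  invisible(x)
}

#' Sample exponential run durations
#'
#' Run durations of an unstimulated run-and-reverse swimmer are exponentially
#' distributed (Poisson reorientation).
#'
#' @param mean_duration mean run duration (s), > 0.
#' @param n number of runs to draw (>= 0).
#' @param seed integer seed.
#' @return Numeric vector of `n` durations (s).
#' @examples
#' mean(generate_run_durations(14.7, 232, seed = 1))
#' @export
generate_run_durations <- function(mean_duration, n, seed = 1L) {
  if (!(mean_duration > 0)) stop("mean_duration must be positive")
  if (n < 0) stop("n must be >= 0")
  set.seed(seed)
  if (n == 0) return(numeric(0))
  rexp(n, rate = 1 / mean_duration)
}

# random orthonormal frame (h, e1, e2); h isotropic on the sphere
random_frame <- function() {
  h <- rnorm(3); h <- h / sqrt(sum(h^2))
  v <- rnorm(3)
  e1 <- v - sum(v * h) * h
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(h[2] * e1[3] - h[3] * e1[2],
          h[3] * e1[1] - h[1] * e1[3],
          h[1] * e1[2] - h[2] * e1[1])
  c(h, e1, e2)
}

#' Generate one synthetic swimmer track
#'
#' The swimmer is represented by a helix axis unit vector subject to
#' rotational diffusion at `D_r` and a phase advancing at `omega`; the
#' instantaneous tangent makes the fixed pitch angle `theta` with the axis.
#' Reversals arrive as a Poisson process at rate `1/tau_run` (or, with a
#' chemotactic response, at the time-dependent rate of [tumble_rate()]) and
#' flip the axis exactly, preserving helix handedness. Translational
#' diffusion and per-frame localization noise are added on top; the noise-free
#' positions are retained in the `"truth"` attribute and the programmed
#' reversal times in `"reversal_times"`, for validation against ground truth.
#'
#' In the noiseless, non-diffusing limit the track is an exact circular helix
#' whose direction correlation is `cos^2(theta) + sin^2(theta) cos(omega tau)`.
#'
#' @param config a [generator_config()].
#' @param response optional [response_params()]; its `sensitivity`, `mode` and
#'   `memory_rate` bias the reversal rate via the concentration experienced
#'   along the track (the base rate is `1/tau_run` from `config`).
#' @param gradient gradient vector of the linear concentration field
#'   `c(r) = gradient . r` (used only when `response` is given).
#' @return A `swim_track` with attributes `truth`, `reversal_times`, `config`.
#' @export
generate_swimmer_track <- function(config, response = NULL,
                                   gradient = c(1, 0, 0)) {
  stopifnot(inherits(config, "generator_config"))
  dt <- 1 / config$frame_rate
  n <- round(config$duration * config$frame_rate)
  if (n < 2) stop("duration must cover at least 2 frames")
  set.seed(config$seed)

  frames <- rotdiff_frames_cpp(n, config$D_r, dt, random_frame())
  phi0 <- runif(1, 0, 2 * pi)
  phi <- phi0 + config$omega * (0:(n - 1)) * dt
  H <- frames[1:n, 1:3, drop = FALSE]
  E1 <- frames[1:n, 4:6, drop = FALSE]
  E2 <- frames[1:n, 7:9, drop = FALSE]
  ct <- cos(config$theta); st <- sin(config$theta)

  if (is.null(response) || response$mode == "none" ||
      response$sensitivity == 0) {
    # unbiased: pre-draw Poisson reversal times
    rev_times <- numeric(0)
    if (is.finite(config$tau_run)) {
      tt <- 0
      repeat {
        gaps <- rexp(32, rate = 1 / config$tau_run)
        rev_times <- c(rev_times, tt + cumsum(gaps))
        tt <- rev_times[length(rev_times)]
        if (tt > config$duration) break
      }
      rev_times <- rev_times[rev_times <= config$duration]
    }
    s <- (-1)^findInterval((0:(n - 1)) * dt, rev_times)
    a <- ct * s * H + st * (cos(phi) * E1 + s * sin(phi) * E2)
    disp <- config$v0 * dt * a
    if (config$D_t > 0)
      disp <- disp + matrix(rnorm(3 * n, sd = sqrt(2 * config$D_t * dt)),
                            ncol = 3)
    truth <- rbind(c(0, 0, 0), apply(disp, 2, cumsum))
  } else {
    # chemotactically biased: step through frames, thinning a Poisson process
    # with the linear-response rate evaluated from the position history
    k <- response$memory_rate
    W <- response$sensitivity
    lambda0 <- 1 / config$tau_run
    e <- exp(-k * dt)
    a0 <- (1 - e) / k
    a1 <- (1 - e * (1 + k * dt)) / k^2
    a2 <- (2 - e * (2 + 2 * k * dt + (k * dt)^2)) / k^3
    S0 <- 0; S1 <- 0; S2 <- 0  # memory pre-filled at c(origin) = 0
    sgn <- 1
    pos <- c(0, 0, 0)
    truth <- matrix(0, n + 1, 3)
    a <- matrix(0, n, 3)
    rev_times <- numeric(0)
    dB <- if (config$D_t > 0)
      matrix(rnorm(3 * n, sd = sqrt(2 * config$D_t * dt)), ncol = 3)
    else NULL
    for (i in seq_len(n)) {
      ci <- sum(gradient * pos)
      S0n <- e * S0
      S1n <- e * (S1 + dt * S0)
      S2n <- e * (S2 + 2 * dt * S1 + dt^2 * S0)
      S0 <- S0n + ci * a0
      S1 <- S1n + ci * a1
      S2 <- S2n + ci * a2
      I <- W * k * (S0 - k * S1 / 2 - k^2 * S2 / 4)
      li <- lambda0 * (1 - I)
      li <- switch(response$mode,
                   lengthen = min(li, lambda0),
                   shorten = max(li, lambda0),
                   bipolar = li)
      li <- max(li, 0)
      if (runif(1) < li * dt) {
        sgn <- -sgn
        rev_times <- c(rev_times, (i - 1) * dt)
      }
      ai <- ct * sgn * H[i, ] + st * (cos(phi[i]) * E1[i, ] +
                                        sgn * sin(phi[i]) * E2[i, ])
      a[i, ] <- ai
      step <- config$v0 * dt * ai
      if (!is.null(dB)) step <- step + dB[i, ]
      pos <- pos + step
      truth[i + 1, ] <- pos
    }
  }

  noisy <- truth + cbind(rnorm(n + 1, sd = config$noise_lateral),
                         rnorm(n + 1, sd = config$noise_lateral),
                         rnorm(n + 1, sd = config$noise_axial))
  tr <- swim_track(sprintf("synthetic_%d", config$seed),
                   t = (0:n) * dt, pos = noisy)
  attr(tr, "truth") <- truth
  attr(tr, "reversal_times") <- rev_times
  attr(tr, "config") <- config
  tr
}

# deterministic per-cell seeds from a master seed
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a population of independent synthetic tracks
#'
#' Per-cell seeds are derived deterministically from the master seed, so the
#' population is reproducible and each track equals the single-track call with
#' its derived seed.
#'
#' @param config a [generator_config()] (its `seed` is ignored in favour of
#'   `seed`).
#' @param n_cells number of tracks (>= 1).
#' @param seed master seed.
#' @inheritParams generate_swimmer_track
#' @return A `track_set` of `n_cells` tracks.
#' @export
generate_population <- function(config, n_cells, seed = config$seed,
                                response = NULL, gradient = c(1, 0, 0)) {
  stopifnot(inherits(config, "generator_config"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  seeds <- derive_seeds(seed, n_cells)
  tracks <- lapply(seq_len(n_cells), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    tr <- generate_swimmer_track(cfg, response = response, gradient = gradient)
    tr$track_id <- sprintf("cell_%03d", i)
    tr
  })
  track_set(tracks)
}
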