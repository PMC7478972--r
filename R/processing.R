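#' Smooth a raw track and filter out unusable segments
#'
#' Reproduces the standard preprocessing of holographically tracked cells:
#' gaps of up to `max_gap` missing frames are linearly interpolated, longer
#' gaps split the track into separate segments, each coordinate is smoothed
#' with a cubic smoothing spline, and segments shorter than `min_duration`
#' are discarded (typically cells entering or leaving the field of view).
#'
#' The spline smoothing strength is chosen per coordinate by the discrepancy
#' principle: the largest smoothing parameter at which the RMS residual does
#' not exceed the localization noise (`noise_lateral` for x,y,
#' `noise_axial` for z). A noise-free track is therefore returned essentially
#' unchanged.
#'
#' @param track a `swim_track` (or a raw track whose times may contain gaps
#'   that are integer multiples of the frame interval).
#' @param max_gap longest gap (frames) to interpolate; longer gaps split.
#' @param min_duration minimum segment duration (s) to keep.
#' @param noise_lateral,noise_axial localization noise s.d. (um) in x,y and z.
#' @param residual_factor the smoothing residual targets
#'   `residual_factor * noise`; the default 1.1 is calibrated on synthetic
#'   ground truth so that finite-difference speeds of the smoothed track are
#'   unbiased (matching the residual to the noise exactly leaves enough
#'   correlated wiggle to inflate speeds at high frame rates).
#' @return A `track_set` of surviving smoothed segments (possibly empty),
#'   with a `discards` attribute logging each rejected segment and reason.
#' @export
smooth_and_filter <- function(track, max_gap = 5, min_duration = 3,
                              noise_lateral = 0.4, noise_axial = 0.5,
                              residual_factor = 1.1) {
  if (length(track$t) < 2) stop("raw track needs at least 2 frames")
  if (any(diff(track$t) <= 0)) stop("track times must be strictly increasing")
  dt <- min(diff(track$t))
  gaps <- round(diff(track$t) / dt) - 1L

  # split at gaps longer than max_gap
  cut_after <- which(gaps > max_gap)
  bounds <- c(0L, cut_after, length(track$t))
  segments <- list()
  discards <- list()
  seg_i <- 0L
  for (b in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[b] + 1L):bounds[b + 1L]
    seg_i <- seg_i + 1L
    id <- if (length(bounds) > 2L)
      sprintf("%s.%d", track$track_id, seg_i) else track$track_id
    tt <- track$t[idx]
    pp <- track$pos[idx, , drop = FALSE]
    if (length(idx) < 2L || diff(range(tt)) < min_duration) {
      discards[[length(discards) + 1L]] <-
        data.frame(track_id = id, reason = "shorter than min_duration",
                   duration_s = diff(range(tt)))
      next
    }
    # interpolate remaining short gaps onto a uniform grid
    tu <- seq(tt[1], tt[length(tt)], by = dt)
    if (length(tu) != length(tt)) {
      pp <- cbind(approx(tt, pp[, 1], xout = tu)$y,
                  approx(tt, pp[, 2], xout = tu)$y,
                  approx(tt, pp[, 3], xout = tu)$y)
      tt <- tu
    }
    sm <- pp
    targets <- residual_factor * c(noise_lateral, noise_lateral, noise_axial)
    if (length(tt) >= 8) {
      for (j in 1:3)
        sm[, j] <- smooth_discrepancy(tt, pp[, j], targets[j])
    }
    segments[[length(segments) + 1L]] <- swim_track(id, tt, sm)
  }
  out <- track_set(segments)
  attr(out, "discards") <- if (length(discards)) do.call(rbind, discards)
  else data.frame(track_id = character(0), reason = character(0),
                  duration_s = numeric(0))
  out
}

# cubic smoothing spline with strength chosen by the discrepancy principle:
# largest spar whose RMS residual stays at or below the target noise level
smooth_discrepancy <- function(t, y, target) {
  fit_rms <- function(spar) {
    f <- smooth.spline(t, y, spar = spar, keep.data = FALSE)
    yy <- predict(f, t)$y
    list(fit = yy, rms = sqrt(mean((y - yy)^2)))
  }
  lo <- -1.5; hi <- 2
  r_lo <- fit_rms(lo)
  if (r_lo$rms >= target) return(r_lo$fit)
  r_hi <- fit_rms(hi)
  # residual below the noise floor even at maximal smoothing: the track has
  # no resolvable noise at this scale, so keep it (essentially) unsmoothed
  if (r_hi$rms <= target) return(r_lo$fit)
  for (i in 1:30) {  # bisection on the monotone residual curve
    mid <- (lo + hi) / 2
    r <- fit_rms(mid)
    if (r$rms > target) hi <- mid else lo <- mid
    if (hi - lo < 1e-3) break
  }
  fit_rms(lo)$fit
}

#' Smooth and filter every track in a set
#'
#' @param tracks a `track_set` of raw tracks.
#' @inheritParams smooth_and_filter
#' @return A `track_set` of all surviving smoothed segments, with the
#'   combined `discards` log as an attribute.
#' @export
process_tracks <- function(tracks, max_gap = 5, min_duration = 3,
                           noise_lateral = 0.4, noise_axial = 0.5,
                           residual_factor = 1.1) {
  res <- lapply(unclass(tracks), smooth_and_filter, max_gap = max_gap,
                min_duration = min_duration, noise_lateral = noise_lateral,
                noise_axial = noise_axial, residual_factor = residual_factor)
  out <- track_set(unlist(lapply(res, unclass), recursive = FALSE))
  attr(out, "discards") <- do.call(rbind, lapply(res, attr, "discards"))
  out
}

#' Classify a track as swimming or diffusing
#'
#' Fits the log-log slope alpha of the mean-squared displacement over lag
#' times in `window`; ballistic swimmers have alpha near 2, diffusing cells
#' near 1. Tracks shorter than the window are labelled `"indeterminate"`.
#'
#' @param track a smoothed `swim_track`.
#' @param window lag-time window (s) for the MSD fit.
#' @param threshold minimum alpha to call a cell swimming.
#' @return One of `"swimming"`, `"diffusing"`, `"indeterminate"`, with the
#'   fitted exponent in the `alpha` attribute.
#' @export
classify_motile <- function(track, window = c(0.1, 2), threshold = 1.5) {
  dt <- track_dt(track)
  n <- nrow(track$pos)
  lag_frames <- unique(round(seq(max(1, window[1] / dt), window[2] / dt,
                                 length.out = 12)))
  lag_frames <- lag_frames[lag_frames < n - 1]
  if (length(lag_frames) < 3 || diff(range(track$t)) < window[2])
    return(structure("indeterminate", alpha = NA_real_))
  msd <- vapply(lag_frames, function(L) {
    d <- track$pos[(1 + L):n, , drop = FALSE] -
      track$pos[1:(n - L), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  alpha <- unname(coef(lm(log(msd) ~ log(lag_frames * dt)))[2])
  structure(if (alpha >= threshold) "swimming" else "diffusing",
            alpha = alpha)
}

#' Reversal statistic of a track
#'
#' The per-frame heuristic
#' `Xi(t) = (|a(t) . a(t+1)| / dt) * [1 - v_t / <v>_t]`
#' combines the alignment of successive tangents with the fractional dip of
#' the instantaneous speed below the track mean: it peaks where a cell slows
#' and turns, i.e. at reversals. The `"angular"` variant replaces the
#' alignment factor with the angular speed `arccos(a . a') / dt`, which
#' grows (rather than stays near 1/dt) at sharp turns.
#'
#' @param track a smoothed `swim_track` with at least 3 frames.
#' @param variant `"printed"` (default) or `"angular"`.
#' @return A list of class `reversal_series`: `xi` (1/s, one value per frame
#'   starting at the second), `t` (frame times of each value), `dt`,
#'   `variant`.
#' @export
reversal_statistic <- function(track, variant = c("printed", "angular")) {
  variant <- match.arg(variant)
  if (length(track$t) < 3) stop("need at least 3 frames")
  dt <- track_dt(track)
  a <- track_tangents(track)
  v <- track_speeds(track)
  vbar <- mean(v)
  if (vbar == 0) stop("degenerate track: mean speed is zero")
  m <- nrow(a)
  dots <- rowSums(a[1:(m - 1), , drop = FALSE] * a[2:m, , drop = FALSE])
  dots <- pmin(pmax(dots, -1), 1)
  bracket <- 1 - v[1:(m - 1)] / vbar
  xi <- switch(variant,
               printed = abs(dots) / dt * bracket,
               angular = acos(dots) / dt * bracket)
  structure(list(xi = xi, t = track$t[2:m], dt = dt, variant = variant),
            class = "reversal_series")
}

#' @export
print.reversal_series <- function(x, ...) {
  cat(sprintf("<reversal_series (%s): %d frames, max Xi = %.3g 1/s>\n",
              x$variant, length(x$xi), max(x$xi)))
  invisible(x)
}

#' Detect reversal events in a reversal series
#'
#' Events are local maxima of Xi above a threshold, subject to a minimum
#' separation (closer candidates are merged, keeping the larger peak).
#'
#' The printed statistic is bounded by `1/dt` (perfectly aligned tangents,
#' complete speed dip), and its speed-dip bracket is already normalized by
#' the track-mean speed, so the default threshold is the scale-invariant
#' `0.5/dt`: an event is called where the speed dips below half the track
#' mean while successive tangents stay aligned. For the unbounded
#' `"angular"` variant the default falls back to `5 * median(|Xi|)`.
#'
#' @param series a [reversal_statistic()] result.
#' @param threshold numeric threshold (1/s) or `"auto"`.
#' @param min_separation minimum time between events (s).
#' @return Numeric vector of event times (s), strictly increasing.
#' @export
detect_reversals <- function(series, threshold = "auto", min_separation = 1) {
  xi <- series$xi
  if (identical(threshold, "auto"))
    threshold <- if (series$variant == "printed") 0.5 / series$dt
    else 5 * median(abs(xi))
  n <- length(xi)
  is_peak <- xi > threshold &
    xi >= c(-Inf, xi[-n]) & xi >= c(xi[-1], -Inf)
  cand <- which(is_peak)
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(xi[cand], decreasing = TRUE)]
  kept <- numeric(0)
  for (i in cand) {
    ti <- series$t[i]
    if (!length(kept) || all(abs(kept - ti) >= min_separation))
      kept <- c(kept, ti)
  }
  sort(kept)
}

#' Segment a track into runs at detected reversals
#'
#' Runs are the straight-swimming intervals between reversal events. The
#' leading and trailing intervals are flagged `censored` (their true duration
#' is unknown because the reversal bounding them was not observed) and should
#' be excluded from duration statistics.
#'
#' @param track a smoothed `swim_track`.
#' @param series optional precomputed [reversal_statistic()]; computed if
#'   `NULL`.
#' @param threshold,min_separation passed to [detect_reversals()].
#' @return A data.frame of class `run_table` with one row per run:
#'   `track_id`, `start_s`, `end_s`, `duration_s`, `censored`,
#'   `dir_x`, `dir_y`, `dir_z` (unit mean direction), `mean_speed`.
#' @export
segment_runs <- function(track, series = NULL, threshold = "auto",
                         min_separation = 1) {
  if (is.null(series)) series <- reversal_statistic(track)
  ev <- detect_reversals(series, threshold, min_separation)
  bounds <- c(track$t[1], ev, track$t[length(track$t)])
  n_runs <- length(bounds) - 1L
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    i0 <- which.min(abs(track$t - bounds[r]))
    i1 <- which.min(abs(track$t - bounds[r + 1]))
    if (i1 <= i0) i1 <- i0 + 1L
    d <- track$pos[i1, ] - track$pos[i0, ]
    nd <- sqrt(sum(d^2))
    dir <- if (nd > 0) d / nd else c(NA_real_, NA_real_, NA_real_)
    sp <- track_speeds(track)[i0:(i1 - 1)]
    out[[r]] <- data.frame(
      track_id = track$track_id,
      start_s = track$t[i0], end_s = track$t[i1],
      duration_s = track$t[i1] - track$t[i0],
      censored = (r == 1L || r == n_runs),
      dir_x = dir[1], dir_y = dir[2], dir_z = dir[3],
      mean_speed = mean(sp))
  }
  res <- do.call(rbind, out)
  class(res) <- c("run_table", "data.frame")
  attr(res, "events") <- ev
  res
}

#' Segment every track in a set into runs
#' @param tracks a `track_set` of smoothed tracks.
#' @inheritParams segment_runs
#' @return A combined `run_table`.
#' @export
segment_all_runs <- function(tracks, threshold = "auto", min_separation = 1) {
  res <- do.call(rbind, lapply(unclass(tracks), function(tr)
    as.data.frame(segment_runs(tr, threshold = threshold,
                               min_separation = min_separation))))
  rownames(res) <- NULL
  class(res) <- c("run_table", "data.frame")
  res
}

#' Exponential fit of run durations
#'
#' Maximum-likelihood exponential mean (the sample mean) with standard error
#' `mean / sqrt(n)`.
#'
#' @param durations run durations (s); censored runs should be excluded.
#' @return A list of class `run_duration_fit`: `tau_run`, `se`, `n_runs`.
#' @export
fit_run_durations <- function(durations) {
  durations <- durations[is.finite(durations)]
  if (!length(durations)) stop("no run durations to fit")
  if (any(durations <= 0)) stop("run durations must be positive")
  n <- length(durations)
  m <- mean(durations)
  structure(list(tau_run = m, se = m / sqrt(n), n_runs = n),
            class = "run_duration_fit")
}

#' @export
print.run_duration_fit <- function(x, ...) {
  cat(sprintf("<run_duration_fit: tau_run = %.3g +/- %.2g s (n = %d)>\n",
              x$tau_run, x$se, x$n_runs))
  invisible(x)
}

#' Gaussian fit of pooled instantaneous speeds
#'
#' @param speeds pooled instantaneous speeds (um/s), n >= 10.
#' @return A list of class `speed_fit`: `mean`, `sd`, `n`.
#' @export
fit_speed_distribution <- function(speeds) {
  speeds <- speeds[is.finite(speeds)]
  if (length(speeds) < 10) stop("need at least 10 speed samples")
  s <- sd(speeds)
  if (s == 0) stop("degenerate speed sample: zero variance")
  structure(list(mean = mean(speeds), sd = s, n = length(speeds)),
            class = "speed_fit")
}

#' @export
print.speed_fit <- function(x, ...) {
  cat(sprintf("<speed_fit: %.3g +/- %.3g um/s (mean +/- s.d., n = %d)>\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Pooled instantaneous speeds of a track set
#' @param tracks a `track_set` (smoothed).
#' @return Numeric vector of all finite instantaneous speeds (um/s).
#' @export
pooled_speeds <- function(tracks) {
  unlist(lapply(unclass(tracks), track_speeds), use.names = FALSE)
}
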