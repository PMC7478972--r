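#' Direction autocorrelation of a track
#'
#' `C(tau) = < a(t) . a(t + tau) >` averaged over frame pairs within the same
#' run: frames within `exclusion` seconds of a reversal are masked, and pairs
#' straddling a reversal are excluded, so the curve reflects persistence
#' during straight runs only.
#'
#' The lag grid is dense (every frame) up to 2 s to resolve the helical
#' oscillation, then logarithmic up to `max_lag` to keep the cost bounded.
#'
#' @param track a smoothed `swim_track`.
#' @param max_lag maximum lag (s); capped at half the track duration.
#' @param reversals reversal event times (s); defaults to the generator
#'   ground truth in `attr(track, "reversal_times")` if present, else none.
#' @param exclusion half-width (s) of the mask around each reversal.
#' @return A data.frame of class `dir_correlation` with columns `lag`,
#'   `value`, `n` (pairs averaged per lag).
#' @export
direction_correlation <- function(track, max_lag = 10, reversals = NULL,
                                  exclusion = 1) {
  dt <- track_dt(track)
  dur <- diff(range(track$t))
  max_lag <- min(max_lag, dur / 2)
  a <- track_tangents(track)
  m <- nrow(a)
  ta <- track$t[seq_len(m)]

  if (is.null(reversals))
    reversals <- attr(track, "reversal_times")
  run_id <- rep(0L, m)
  ok <- rep(TRUE, m)
  if (length(reversals)) {
    run_id <- findInterval(ta, sort(reversals))
    for (rv in reversals) ok <- ok & abs(ta - rv) > exclusion
  }
  ok <- ok & apply(is.finite(a), 1, all)

  lag_frames <- unique(c(0:min(round(2 / dt), floor(max_lag / dt)),
                         round(exp(seq(log(max(1, round(2 / dt))),
                                       log(max(1, floor(max_lag / dt))),
                                       length.out = 40)))))
  lag_frames <- sort(lag_frames[lag_frames <= floor(max_lag / dt)])

  res <- lapply(lag_frames, function(L) {
    if (L == 0) return(c(value = 1, n = sum(ok)))
    i <- seq_len(m - L)
    use <- ok[i] & ok[i + L] & run_id[i] == run_id[i + L]
    if (!any(use)) return(c(value = NA_real_, n = 0))
    c(value = mean(rowSums(a[i, , drop = FALSE][use, , drop = FALSE] *
                             a[i + L, , drop = FALSE][use, , drop = FALSE])),
      n = sum(use))
  })
  out <- data.frame(lag = lag_frames * dt,
                    value = vapply(res, `[[`, numeric(1), "value"),
                    n = vapply(res, `[[`, numeric(1), "n"))
  out <- out[out$n > 0, ]
  if (nrow(out) < length(lag_frames))
    warning("correlation curve truncated: insufficient frames at long lags")
  class(out) <- c("dir_correlation", "data.frame")
  out
}

# the helical-plus-Brownian correlation model
helical_model <- function(lag, D_r, theta, omega) {
  exp(-2 * D_r * lag) * (cos(theta)^2 + sin(theta)^2 * cos(omega * lag))
}

#' Fit the helical direction-correlation model
#'
#' Least-squares fit of
#' `C(tau) = exp(-2 D_r tau) [cos^2 theta + sin^2 theta cos(omega tau)]`
#' to a measured correlation curve. The model superposes an exponential decay
#' from rotational Brownian motion of the helix axis with an undamped
#' oscillation from the helical body motion; fitting the pure-Brownian
#' `model = "brownian"` form `exp(-2 D_r tau)` to helical data overestimates
#' `D_r`, which is the motivation for the full model.
#'
#' The oscillation frequency is unknown a priori, so the fit is multi-started
#' over a logarithmic grid of `omega` values between one cycle per curve
#' length and the Nyquist rate; the best residual wins.
#'
#' @param curve a [direction_correlation()] data.frame (columns `lag`,
#'   `value`, and optionally `n`).
#' @param model `"helical"` (default) or `"brownian"` (theta fixed at 0).
#' @param weights use per-lag pair counts as weights (if present).
#' @param n_starts number of omega starting values.
#' @return A list of class `helical_fit`: `D_r`, `theta`, `omega`, `tau_r`
#'   (= 1/(2 D_r)), `rms` (residual RMS), `model`.
#' @export
fit_helical_correlation <- function(curve, model = c("helical", "brownian"),
                                    weights = TRUE, n_starts = 8) {
  model <- match.arg(model)
  curve <- curve[is.finite(curve$value), ]
  if (nrow(curve) < 10) stop("need at least 10 lags to fit")
  lag <- curve$lag
  y <- curve$value
  w <- if (weights && !is.null(curve$n)) curve$n / mean(curve$n)
  else rep(1, length(y))

  pos <- lag > 0 & y > 0.05
  Dr0 <- if (any(pos)) max(0, median(-log(y[pos]) / (2 * lag[pos])))
  else 0.01

  if (model == "brownian") {
    obj <- function(p) sum(w * (exp(-2 * exp(p) * lag) - y)^2)
    # log-parameterized rate; also try a fit pinned near zero decay
    cands <- lapply(log(pmax(c(Dr0, 0.01, 0.1), 1e-8)), function(p0)
      optim(p0, obj, method = "BFGS",
            control = list(reltol = 1e-14, maxit = 500)))
    zero_ssr <- sum(w * (1 - y)^2)
    best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "value"))]]
    if (zero_ssr < best$value) {
      Dr <- 0; ssr <- zero_ssr
    } else {
      Dr <- exp(best$par); ssr <- best$value
    }
    fitted <- exp(-2 * Dr * lag)
    return(structure(list(
      D_r = Dr, theta = 0, omega = NA_real_,
      tau_r = if (Dr > 0) 1 / (2 * Dr) else Inf,
      rms = sqrt(sum(w * (fitted - y)^2) / sum(w)),
      model = model), class = "helical_fit"))
  }

  dlag <- min(diff(lag))
  om_lo <- 2 * pi / max(lag)
  om_hi <- pi / dlag
  starts <- exp(seq(log(om_lo), log(om_hi), length.out = n_starts))
  obj <- function(p) {
    f <- helical_model(lag, p[1], p[2], p[3])
    sum(w * (f - y)^2)
  }
  fits <- lapply(starts, function(om0) {
    tryCatch(
      optim(c(max(Dr0, 1e-4), 0.3, om0), obj, method = "L-BFGS-B",
            lower = c(0, 0, om_lo / 4), upper = c(10, pi / 2, om_hi * 2),
            control = list(factr = 1e2, maxit = 500)),
      error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (!length(fits))
    stop("helical correlation fit failed to converge from all starts")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  p <- best$par
  # nested candidate: the pure-exponential (theta = 0) solution, so the fit
  # reduces exactly to the Brownian model when the oscillation is absent
  bfit <- fit_helical_correlation(curve, model = "brownian",
                                  weights = weights)
  if (obj(c(bfit$D_r, 0, starts[1])) <= best$value)
    p <- c(bfit$D_r, 0, starts[1])
  fitted <- helical_model(lag, p[1], p[2], p[3])
  structure(list(
    D_r = p[1], theta = p[2], omega = p[3],
    tau_r = if (p[1] > 0) 1 / (2 * p[1]) else Inf,
    rms = sqrt(sum(w * (fitted - y)^2) / sum(w)),
    model = model), class = "helical_fit")
}

#' @export
print.helical_fit <- function(x, ...) {
  cat(sprintf(
    "<helical_fit (%s): D_r = %.4g 1/s (tau_r = %.3g s), omega = %.3g rad/s, theta = %.3g rad, rms = %.2g>\n",
    x$model, x$D_r, x$tau_r, x$omega, x$theta, x$rms))
  invisible(x)
}

#' Rotational relaxation time from a rotational diffusivity
#'
#' `tau_r = 1 / (2 D_r)`, the time scale on which Brownian rotation
#' randomizes a cell's orientation.
#'
#' @param D_r rotational diffusivity (1/s), > 0.
#' @return Relaxation time (s).
#' @examples
#' rotational_relaxation(0.081)  # 6.17 s
#' @export
rotational_relaxation <- function(D_r) {
  if (!(D_r > 0)) stop("D_r must be positive")
  1 / (2 * D_r)
}

#' Log-normal fit of a population of rotational diffusivities
#'
#' Maximum-likelihood log-normal parameters and the modal value
#' `exp(meanlog - sdlog^2)`; per-track D_r estimates are typically
#' right-skewed and summarized by their mode.
#'
#' @param values positive values (e.g. per-track D_r), n >= 10.
#' @return A list of class `lognormal_fit`: `meanlog`, `sdlog`, `mode`, `n`.
#' @export
fit_lognormal <- function(values) {
  values <- values[is.finite(values)]
  if (any(values <= 0)) stop("all values must be positive")
  if (length(values) < 10) stop("need at least 10 values")
  lx <- log(values)
  n <- length(lx)
  meanlog <- mean(lx)
  sdlog <- sqrt(mean((lx - meanlog)^2))  # MLE
  structure(list(meanlog = meanlog, sdlog = sdlog,
                 mode = exp(meanlog - sdlog^2), n = n),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "<lognormal_fit: meanlog = %.3g, sdlog = %.3g, mode = %.4g (n = %d)>\n",
    x$meanlog, x$sdlog, x$mode, x$n))
  invisible(x)
}

#' Per-track helical fits for a track set
#'
#' Convenience wrapper: direction correlation and helical fit per track,
#' returned as a table.
#'
#' @param tracks a `track_set`.
#' @param max_lag maximum correlation lag (s).
#' @param ... passed to [fit_helical_correlation()].
#' @return data.frame with columns `track_id`, `D_r`, `omega`, `theta`,
#'   `tau_r`, `rms`.
#' @export
fit_orientation_population <- function(tracks, max_lag = 10, ...) {
  rows <- lapply(unclass(tracks), function(tr) {
    fit <- tryCatch({
      cc <- direction_correlation(tr, max_lag = max_lag)
      fit_helical_correlation(cc, ...)
    }, error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(track_id = tr$track_id, D_r = fit$D_r, omega = fit$omega,
               theta = fit$theta, tau_r = fit$tau_r, rms = fit$rms)
  })
  res <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(res) <- NULL
  res
}
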