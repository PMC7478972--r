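# Shared fixtures built in code: small deterministic tracks and helpers for
# comparing pipeline output against generator ground truth.

# straight constant-velocity track along `dir`
straight_track <- function(v0 = 2, duration = 10, frame_rate = 50,
                           dir = c(1, 0, 0), id = "straight") {
  t <- seq(0, duration, by = 1 / frame_rate)
  swim_track(id, t, outer(t * v0, dir / sqrt(sum(dir^2))))
}

# helical run-reverse track with reversals programmed at known times
# (reflects the noise-free generator path, then adds fresh noise)
programmed_reversal_track <- function(rev_times, duration = 60, v0 = 2,
                                      noise = 0.05, seed = 5) {
  cfg <- generator_config(v0 = v0, tau_run = Inf, D_r = 0.02, D_t = 0.01,
                          duration = duration, noise_lateral = 0,
                          noise_axial = 0, seed = seed)
  tr <- generate_swimmer_track(cfg)
  p <- attr(tr, "truth")
  dt <- track_dt(tr)
  d <- diff(p)
  s <- (-1)^findInterval(seq_len(nrow(d)) * dt - dt / 2, sort(rev_times))
  p2 <- rbind(c(0, 0, 0), apply(d * s, 2, cumsum))
  noisy <- p2 + cbind(rnorm(nrow(p2), sd = noise),
                      rnorm(nrow(p2), sd = noise),
                      rnorm(nrow(p2), sd = noise * 1.25))
  out <- swim_track("programmed", tr$t, noisy)
  attr(out, "truth") <- p2
  attr(out, "reversal_times") <- sort(rev_times)
  out
}

# run table from generator ground truth (reversal times + noise-free path)
runs_from_truth <- function(track) {
  rv <- attr(track, "reversal_times")
  truth <- attr(track, "truth")
  t <- track$t
  bounds <- c(t[1], rv, t[length(t)])
  rows <- lapply(seq_len(length(bounds) - 1L), function(r) {
    i0 <- which.min(abs(t - bounds[r]))
    i1 <- which.min(abs(t - bounds[r + 1]))
    if (i1 <= i0) return(NULL)
    d <- truth[i1, ] - truth[i0, ]
    nd <- sqrt(sum(d^2))
    if (nd == 0) return(NULL)
    data.frame(track_id = track$track_id,
               start_s = bounds[r], end_s = bounds[r + 1],
               duration_s = bounds[r + 1] - bounds[r],
               censored = (r == 1L || r == length(bounds) - 1L),
               dir_x = d[1] / nd, dir_y = d[2] / nd, dir_z = d[3] / nd,
               mean_speed = nd / (bounds[r + 1] - bounds[r]))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

# random 3D rotation matrix (Haar-ish via QR)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_track <- function(track, R, shift = c(0, 0, 0)) {
  swim_track(track$track_id, track$t,
             sweep(track$pos %*% t(R), 2, -shift))
}
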