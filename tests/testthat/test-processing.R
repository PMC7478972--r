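test_that("short tracks are rejected and clean tracks pass through", {
  short <- straight_track(duration = 2.9)
  out <- smooth_and_filter(short)
  expect_length(out, 0)
  expect_equal(attr(out, "discards")$reason, "shorter than min_duration")

  clean <- straight_track(duration = 10)
  out <- smooth_and_filter(clean)
  expect_length(out, 1)
  expect_lt(max(abs(out[[1]]$pos - clean$pos)), 1e-6)

  bad <- clean
  bad$t[5] <- bad$t[7]
  expect_error(smooth_and_filter(bad), "increasing")
})

test_that("gaps are interpolated up to max_gap and split beyond it", {
  tr <- straight_track(duration = 10)
  # remove 3 interior frames: linear interpolation restores them
  keep <- setdiff(seq_along(tr$t), 101:103)
  gappy <- swim_track("gap3", tr$t[keep], tr$pos[keep, ], validate = FALSE)
  out <- smooth_and_filter(gappy)
  expect_length(out, 1)
  expect_equal(length(out[[1]]$t), length(tr$t))
  expect_lt(max(abs(out[[1]]$pos - tr$pos)), 1e-6)

  # remove 8 interior frames: track splits into two segments
  keep <- setdiff(seq_along(tr$t), 201:208)
  gappy <- swim_track("gap8", tr$t[keep], tr$pos[keep, ], validate = FALSE)
  out <- smooth_and_filter(gappy)
  expect_length(out, 2)
})

test_that("smoothing a noisy track recovers the noise-free path", {
  set.seed(1)
  cfg <- generator_config(v0 = 1.9, duration = 60, seed = 42)
  tr <- generate_swimmer_track(cfg)
  sm <- smooth_and_filter(tr)[[1]]
  rms <- sqrt(mean(rowSums((sm$pos - attr(tr, "truth"))^2) / 3))
  expect_lt(rms, 0.4)
})

test_that("MSD exponent separates swimming from diffusing cells", {
  expect_equal(as.character(classify_motile(straight_track())), "swimming")
  expect_equal(attr(classify_motile(straight_track()), "alpha"), 2,
               tolerance = 1e-6)

  swim <- generate_swimmer_track(generator_config(duration = 30, seed = 6))
  expect_equal(as.character(classify_motile(smooth_and_filter(swim)[[1]])),
               "swimming")

  diff_cfg <- generator_config(v0 = 0, D_t = 0.3, duration = 30,
                               noise_lateral = 0.05, noise_axial = 0.05,
                               seed = 7)
  diffusing <- generate_swimmer_track(diff_cfg)
  expect_equal(as.character(classify_motile(
    smooth_and_filter(diffusing, noise_lateral = 0.05,
                      noise_axial = 0.05)[[1]])), "diffusing")

  tiny <- straight_track(duration = 1)
  expect_equal(as.character(classify_motile(tiny)), "indeterminate")
})

test_that("Xi vanishes on constant-speed runs and hits 1/dt at a full stop", {
  tr <- straight_track(v0 = 2, duration = 5)
  ser <- reversal_statistic(tr)
  expect_lt(max(abs(ser$xi)), 1e-9)

  # one near-zero-speed frame with collinear directions: Xi = 1/dt = 50
  pos <- cbind(c(0, 1e-12, 1, 2), 0, 0)
  tr2 <- swim_track("stop", (0:3) * 0.02, pos)
  ser2 <- reversal_statistic(tr2)
  expect_equal(ser2$xi[1], 50, tolerance = 1e-6)

  expect_error(reversal_statistic(swim_track("z", c(0, 0.02, 0.04),
                                             matrix(1, 3, 3))), "degenerate")
})

test_that("Xi is bounded by 1/dt and invariant under rigid motions", {
  set.seed(3)
  tr <- generate_swimmer_track(generator_config(duration = 20, seed = 8))
  sm <- smooth_and_filter(tr)[[1]]
  ser <- reversal_statistic(sm)
  expect_lte(max(ser$xi), 1 / ser$dt + 1e-9)

  moved <- rotate_track(sm, random_rotation(), shift = c(5, -3, 11))
  expect_equal(reversal_statistic(moved)$xi, ser$xi, tolerance = 1e-9)
})

test_that("reversal events are localized at programmed reversals", {
  set.seed(2)
  tr <- programmed_reversal_track(c(15, 30, 45))
  sm <- smooth_and_filter(tr, noise_lateral = 0.05,
                          noise_axial = 0.0625)[[1]]
  ser <- reversal_statistic(sm)
  # global argmax sits at a programmed reversal
  t_max <- ser$t[which.max(ser$xi)]
  expect_lt(min(abs(t_max - c(15, 30, 45))), 2 * ser$dt + 1e-9)

  runs <- segment_runs(sm, ser)
  ev <- attr(runs, "events")
  expect_length(ev, 3)
  expect_lt(max(abs(sort(ev) - c(15, 30, 45))), 2 * ser$dt + 1e-9)
  # interior run durations match the programmed 15 s spacing
  expect_lt(max(abs(runs$duration_s[!runs$censored] - 15)),
            4 * ser$dt + 1e-9)

  # full-noise track still localizes events within half a second
  set.seed(4)
  tr2 <- programmed_reversal_track(c(15, 30, 45), noise = 0.4)
  sm2 <- smooth_and_filter(tr2)[[1]]
  ev2 <- attr(segment_runs(sm2), "events")
  expect_length(ev2, 3)
  expect_lt(max(abs(sort(ev2) - c(15, 30, 45))), 0.5)
})

test_that("segmentation censors track ends and merges close events", {
  tr <- straight_track(duration = 10)
  runs <- segment_runs(tr)
  expect_equal(nrow(runs), 1L)
  expect_true(runs$censored)

  # two events 0.5 s apart are merged by the minimum-separation rule
  set.seed(5)
  tr2 <- programmed_reversal_track(c(30, 30.5))
  sm2 <- smooth_and_filter(tr2, noise_lateral = 0.05,
                           noise_axial = 0.0625)[[1]]
  ev <- attr(segment_runs(sm2), "events")
  expect_length(ev, 1)
})

test_that("segmentation finds the same events on a time-reversed track", {
  set.seed(6)
  tr <- programmed_reversal_track(c(20, 40))
  sm <- smooth_and_filter(tr, noise_lateral = 0.05,
                          noise_axial = 0.0625)[[1]]
  ev <- attr(segment_runs(sm), "events")
  n <- length(sm$t)
  rev_tr <- swim_track("rev", sm$t, sm$pos[n:1, ])
  ev_rev <- attr(segment_runs(rev_tr), "events")
  Tend <- sm$t[n]
  expect_equal(sort(ev), sort(Tend - ev_rev), tolerance = 3 * track_dt(sm))
})

test_that("run-duration MLE is the sample mean with se = mean/sqrt(n)", {
  f <- fit_run_durations(c(5, 5, 5))
  expect_equal(f$tau_run, 5)
  expect_equal(f$se, 5 / sqrt(3))
  expect_error(fit_run_durations(numeric(0)), "no run durations")

  x <- generate_run_durations(7.3, 500, seed = 2)
  expect_identical(fit_run_durations(x)$tau_run, mean(x))

  # recovery at the two experimental sample sizes
  hx <- fit_run_durations(generate_run_durations(14.7, 232, seed = 14))
  expect_lt(abs(hx$tau_run - 14.7), 3 * hx$se)
  hg <- fit_run_durations(generate_run_durations(12.1, 659, seed = 15))
  expect_lt(abs(hg$tau_run - 12.1), 3 * hg$se)
})

test_that("speed distribution fit recovers Gaussian parameters", {
  expect_error(fit_speed_distribution(rep(2, 100)), "zero variance")
  expect_error(fit_speed_distribution(1:5), "at least 10")
  set.seed(8)
  x <- rnorm(1e5, 2.2, 0.8)
  f <- fit_speed_distribution(x)
  expect_lt(abs(f$mean - 2.2) / 2.2, 0.01)
  expect_lt(abs(f$sd - 0.8) / 0.8, 0.01)
})

test_that("full pipeline recovers generating run duration and speed", {
  cfg <- generator_config(v0 = 2, tau_run = 12, duration = 90, seed = 7)
  pop <- generate_population(cfg, 25, seed = 7)
  sm <- process_tracks(pop)
  runs <- segment_all_runs(sm)
  fit <- fit_run_durations(runs$duration_s[!runs$censored])
  expect_lt(abs(fit$tau_run - 12), 3 * fit$se)
  sp <- fit_speed_distribution(pooled_speeds(sm))
  expect_lt(abs(sp$mean - 2) / 2, 0.1)
})
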