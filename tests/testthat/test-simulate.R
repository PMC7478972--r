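test_that("configuration validation catches invalid discretizations", {
  expect_error(sim_config(tau_run = 0.2, dt = 0.033), "below 0.1")
  expect_error(sim_config(duration = 0.01), "duration")
  expect_error(sim_config(n_cells = 0), "n_cells")
  expect_error(sim_config(mode = "bipolar", gradient = c(0, 0, 0)),
               "gradient")
})

test_that("ensembles are bit-reproducible under a seed", {
  cfg <- sim_config(n_cells = 5, duration = 50, mode = "bipolar", seed = 3,
                    store_reversals = TRUE)
  r1 <- simulate_ensemble(cfg)
  r2 <- simulate_ensemble(cfg)
  expect_identical(r1$positions, r2$positions)
  expect_identical(r1$reversal_times, r2$reversal_times)
})

test_that("deterministic limit is exact straight-line motion", {
  cfg <- sim_config(v0 = 2, tau_run = Inf, D_r = 0, D_t = 0,
                    duration = 100, n_cells = 3, equilibration = 0, seed = 1)
  res <- simulate_ensemble(cfg)
  t_end <- res$times[length(res$times)]  # duration rounds to whole steps
  for (cell in 1:3) {
    p_end <- res$positions[length(res$times), , cell]
    expect_equal(sqrt(sum(p_end^2)), 2 * t_end, tolerance = 1e-9)
  }
})

test_that("unstimulated reversals arrive at the configured Poisson rate", {
  cfg <- sim_config(tau_run = 14.7, mode = "none", n_cells = 50,
                    duration = 1000, seed = 5)
  res <- simulate_ensemble(cfg)
  total <- sum(res$n_reversals)
  expected <- 50 * 1000 / 14.7
  expect_lt(abs(total - expected), 3 * sqrt(expected))
})

test_that("direction correlation decays at 2 D_r + 2 lambda", {
  cfg <- sim_config(tau_run = 14.7, D_r = 0.08, D_t = 0, mode = "none",
                    n_cells = 80, duration = 400, record_dt = 0.165,
                    store_directions = TRUE, seed = 6)
  res <- simulate_ensemble(cfg)
  D <- res$directions
  nt <- dim(D)[1]
  lags <- round(c(0.5, 1, 2, 3) / 0.165)
  cors <- vapply(lags, function(L) {
    mean(vapply(seq_len(dim(D)[3]), function(c)
      mean(rowSums(D[1:(nt - L), , c] * D[(1 + L):nt, , c])), numeric(1)))
  }, numeric(1))
  rate <- -coef(lm(log(cors) ~ I(lags * 0.165)))[[2]]
  expect_lt(abs(rate - (2 * 0.08 + 2 / 14.7)) / (2 * 0.08 + 2 / 14.7), 0.1)
})

test_that("unbiased swimmers show no drift and isotropic spreading", {
  cfg <- sim_config(mode = "none", n_cells = 100, duration = 2000, seed = 7)
  res <- simulate_ensemble(cfg)
  for (i in 1:3)
    expect_lt(abs(res$drift$v[i]), 3 * res$drift$se[i])
  # MSD identical along x, y, z within sampling error
  msd_axis <- vapply(1:3, function(j) {
    mean((res$positions[length(res$times), j, ] -
            res$positions[1, j, ])^2)
  }, numeric(1))
  expect_lt(max(msd_axis) / min(msd_axis), 1.8)
})

test_that("MSD shows the ballistic and diffusive regimes", {
  # non-motile cells: <x^2>/tau is flat at 2 D_t
  cfg <- sim_config(v0 = 0, tau_run = Inf, D_r = 0, D_t = 0.1,
                    n_cells = 200, duration = 400, equilibration = 0,
                    seed = 8)
  res <- simulate_ensemble(cfg)
  msd <- msd_along_gradient(res, from_origin = FALSE)
  mid <- msd[msd$tau > 5 & msd$tau < 100, ]
  expect_lt(max(abs(mid$msd_over_tau / (2 * 0.1) - 1)), 0.1)
  expect_lt(max(abs(mid$alpha), na.rm = TRUE), 0.25)

  # ballistic swimmers at short lag: <x^2(tau)> = (v0^2/3) tau^2
  cfg2 <- sim_config(v0 = 2, tau_run = Inf, D_r = 0, D_t = 0,
                     n_cells = 400, duration = 10, record_dt = 0.5,
                     equilibration = 0, seed = 9)
  res2 <- simulate_ensemble(cfg2)
  msd2 <- msd_along_gradient(res2, from_origin = TRUE)
  sel <- msd2[msd2$tau >= 2, ]
  expect_lt(max(abs(sel$msd / (4 / 3 * sel$tau^2) - 1)), 0.1)

  # long-lag effective diffusivity D_eff = v0^2 / (3 (2 D_r + 2 lambda))
  cfg3 <- sim_config(v0 = 2, tau_run = 14.7, D_r = 0.08, D_t = 0,
                     mode = "none", n_cells = 100, duration = 2000, seed = 10)
  res3 <- simulate_ensemble(cfg3)
  msd3 <- msd_along_gradient(res3, from_origin = FALSE)
  pred <- 2^2 / (3 * (2 * 0.08 + 2 / 14.7))
  sel3 <- msd3[msd3$tau > 100 & msd3$tau < 400, ]
  expect_lt(max(abs(sel3$msd_over_tau / (2 * pred) - 1)), 0.15)
})

test_that("drift velocity fit is exact on linear input and needs 10 points", {
  tt <- seq(0, 10, by = 0.5)
  r_avg <- cbind(0.2 * tt, 0 * tt, 0 * tt)
  v <- drift_velocity(tt, r_avg)
  expect_equal(v$v, c(0.2, 0, 0), tolerance = 1e-12)
  expect_error(drift_velocity(tt[1:5], r_avg[1:5, ]), "at least 10")
})

test_that("efficiency algebra and friction scaling", {
  expect_equal(chemotactic_efficiency(0, 2, 0.03)$epsilon, 0)
  e1 <- chemotactic_efficiency(0.2, 2, 0.03)
  e2 <- chemotactic_efficiency(0.2, 4, 0.03)
  expect_equal(e1$epsilon_gamma / e2$epsilon_gamma, 4)
  expect_equal(e1$power, 0.03 * 4)
  expect_error(chemotactic_efficiency(0.1, 0, 0.03), "v0")
})

test_that("bipolar response outperforms the one-sided modes", {
  fds <- ses <- numeric(0)
  for (mode in c("bipolar", "lengthen", "shorten")) {
    cfg <- sim_config(mode = mode, n_cells = 50, duration = 2000, seed = 11)
    res <- simulate_ensemble(cfg)
    fds[mode] <- res$fractional_drift
    ses[mode] <- res$drift$se[1] / cfg$v0
  }
  expect_gt(fds["bipolar"],
            fds["lengthen"] - 3 * sqrt(ses["bipolar"]^2 + ses["lengthen"]^2))
  expect_gt(fds["bipolar"],
            fds["shorten"] - 3 * sqrt(ses["bipolar"]^2 + ses["shorten"]^2))
})

test_that("drift is linear in the sensitivity well below saturation", {
  run <- function(beta, seed) {
    cfg <- sim_config(mode = "bipolar", beta = beta, n_cells = 250,
                      duration = 5000, seed = seed)
    res <- simulate_ensemble(cfg)
    c(fd = res$fractional_drift, se = res$drift$se[1] / cfg$v0)
  }
  lo <- run(0.45, 12)
  hi <- run(0.9, 13)
  # doubling the sensitivity doubles the drift within 10% plus noise
  tol <- 0.1 * hi[["fd"]] + 3 * sqrt(hi[["se"]]^2 + 4 * lo[["se"]]^2)
  expect_lt(abs(hi[["fd"]] - 2 * lo[["fd"]]), tol)

  # with the calibrated sensitivity the rate floor is essentially never hit
  cfg <- sim_config(mode = "bipolar", n_cells = 20, duration = 1000,
                    seed = 14)
  expect_lt(simulate_ensemble(cfg)$floored_fraction, 0.01)
})

test_that("tumble reorientation draws bounded gamma angles", {
  cfg <- sim_config(v0 = 20, tau_run = 1, D_r = 0.08, dt = 0.02,
                    reorientation = "tumble", mode = "none",
                    n_cells = 30, duration = 100, record_dt = 0.02,
                    store_directions = TRUE, store_reversals = TRUE, seed = 15)
  res <- simulate_ensemble(cfg)
  # turning angles at tumble events follow the configured mean (68 deg)
  angs <- c()
  for (cell in seq_len(30)) {
    ev <- res$reversal_times[[cell]]
    idx <- round(ev / 0.02)  # direction index just before the tumble
    idx <- idx[idx >= 1 & idx < length(res$times)]
    for (i in idx) {
      d <- sum(res$directions[i, , cell] * res$directions[i + 1, , cell])
      angs <- c(angs, acos(pmin(pmax(d, -1), 1)))
    }
  }
  expect_gt(length(angs), 500)
  # observed mean angle: tumble angle plus one rotational-diffusion step
  expect_lt(abs(mean(angs) - 68 * pi / 180), 0.1)
  expect_lte(max(angs), pi)
})
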