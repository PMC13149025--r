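test_that("trajectory building: gap truncation and prefilters", {
  p <- track_filter_params(min_locs = 200, max_gap = 18, efo_max = 130000)
  t <- seq_len(500) * 2e-3
  t[301:500] <- t[301:500] + 25e-3  # 25 ms gap after localization 300
  tab <- loc_table(x = rnorm(500), y = rnorm(500), z = rnorm(500),
                   trace_id = 1L, t = t)
  built <- build_trajectories(tab, p)
  expect_length(built$trajectories, 1L)
  expect_equal(nrow(built$trajectories[[1]]), 300L)
  expect_equal(built$log$truncated, 1L)

  short <- loc_table(x = rnorm(150), y = rnorm(150), z = rnorm(150),
                     trace_id = 2L, t = seq_len(150) * 2e-3)
  expect_length(build_trajectories(short, p)$trajectories, 0L)

  hot <- loc_table(x = rnorm(300), y = rnorm(300), z = rnorm(300),
                   trace_id = 3L, t = seq_len(300) * 2e-3, efo = 150000)
  res <- build_trajectories(hot, p)
  expect_length(res$trajectories, 0L)
  expect_equal(res$log$dropped_efo, 1L)
})

test_that("MSD: stationary, ballistic closed form, invariances", {
  p <- track_filter_params()
  still <- data.frame(t = seq_len(100) * 7e-3, x = 5, y = -2, z = 1,
                      efo = 7e4)
  curve <- compute_msd(still, p)
  expect_true(all(curve$msd_um2 == 0))

  # constant velocity 1 nm/ms sampled every 7 ms (= bin width): each bin
  # holds a single lag, MSD(tau) = tau^2 exactly
  n <- 60
  ball <- data.frame(t = seq_len(n) * 7e-3, x = seq_len(n) * 7, y = 0, z = 0,
                     efo = 7e4)
  bc <- compute_msd(ball, p)
  expect_equal(bc$lag_ms, 7 * seq_len(nrow(bc)), tolerance = 1e-9)
  expect_equal(bc$msd_um2 * 1e6, bc$lag_ms^2, tolerance = 1e-9)

  # rigid translation leaves the curve unchanged; scaling by k scales
  # the MSD by k^2
  traj <- data.frame(t = seq_len(80) * 5e-3,
                     x = cumsum(rnorm(80, 0, 5)),
                     y = cumsum(rnorm(80, 0, 5)),
                     z = cumsum(rnorm(80, 0, 5)), efo = 7e4)
  c0 <- compute_msd(traj, p)
  shifted <- traj; shifted$x <- shifted$x + 1e4; shifted$z <- shifted$z - 2e3
  expect_equal(compute_msd(shifted, p), c0)
  scaled <- traj
  scaled[, c("x", "y", "z")] <- scaled[, c("x", "y", "z")] * 3
  cs <- compute_msd(scaled, p)
  expect_equal(cs$msd_um2, c0$msd_um2 * 9, tolerance = 1e-12)
})

test_that("diffusion fit: exact line, weighting, refusal, oracle", {
  p <- track_filter_params()
  curve <- data.frame(lag_ms = seq(7, 343, by = 7))
  curve$msd_um2 <- 6 * 0.01 * curve$lag_ms / 1000
  curve$n_pairs <- sample(1:50, nrow(curve), replace = TRUE)
  expect_equal(fit_diffusion(curve, c(5, 50))$d, 0.01, tolerance = 1e-12)
  flat <- curve; flat$n_pairs <- 1L
  expect_equal(fit_diffusion(flat, c(5, 50))$d,
               fit_diffusion(curve, c(5, 50))$d, tolerance = 1e-12)

  refuse <- fit_diffusion(curve[1, ], c(5, 50))
  expect_true(is.na(refuse$d))
  expect_match(refuse$reason, "fewer than 2")

  # independent normal-equations oracle on noisy weighted data
  set.seed(12)
  noisy <- curve
  noisy$msd_um2 <- noisy$msd_um2 + rnorm(nrow(noisy), 0, 1e-4)
  for (win in list(c(5, 50), c(50, 350))) {
    use <- noisy$lag_ms >= win[1] & noisy$lag_ms <= win[2]
    tau <- noisy$lag_ms[use] / 1000; y <- noisy$msd_um2[use]
    w <- noisy$n_pairs[use]
    oracle_d <- sum(w * tau * y) / sum(w * tau^2) / 6
    expect_equal(fit_diffusion(noisy, win)$d, oracle_d, tolerance = 1e-12)
  }
})

test_that("static noise inflates the zero-intercept micro fit as predicted", {
  sigma <- 15; d <- 0.01
  trk <- simulate_tracks(track_config(n_tracks = 120, d_true = d, dt_ms = 2,
                                      n_locs = 300, loc_sigma = sigma,
                                      rng_seed = 55))
  built <- build_trajectories(trk$localizations,
                              track_filter_params(min_locs = 250))
  ens <- ensemble_msd(built$trajectories, track_filter_params(min_locs = 250))
  use <- ens$curve$lag_ms >= 5 & ens$curve$lag_ms <= 50
  tau <- ens$curve$lag_ms[use] / 1000
  w <- ens$curve$n_pairs[use]
  offset_pred <- (6 * sigma^2 / 1e6) * sum(w * tau) / sum(w * tau^2) / 6
  expect_equal(ens$fit_micro$d - d, offset_pred, tolerance = 0.25)
  expect_gt(ens$fit_micro$d, d)
})

test_that("ensemble weighting consistency and bimodal mixtures", {
  p <- track_filter_params(min_locs = 50)
  trk <- simulate_tracks(track_config(n_tracks = 1, d_true = 0.01,
                                      n_locs = 300, rng_seed = 61))
  tr <- build_trajectories(trk$localizations, p)$trajectories
  ens <- ensemble_msd(c(tr, tr), p)
  single <- compute_msd(tr[[1]], p)
  expect_equal(ens$curve$msd_um2, single$msd_um2, tolerance = 1e-12)
  expect_equal(ens$curve$lag_ms, single$lag_ms, tolerance = 1e-12)

  # two-population mixture separates in per-trajectory micro D
  slow <- simulate_tracks(track_config(n_tracks = 40, d_true = 0.004,
                                       dt_ms = 2, n_locs = 400,
                                       loc_sigma = 0, rng_seed = 62))
  fast <- simulate_tracks(track_config(n_tracks = 40, d_true = 0.02,
                                       dt_ms = 2, n_locs = 400,
                                       loc_sigma = 0, rng_seed = 63))
  fast$localizations$trace_id <- fast$localizations$trace_id + 1000L
  tab <- rbind(slow$localizations, fast$localizations)
  per <- fit_trajectories(build_trajectories(tab, p)$trajectories, p)
  lab <- per$track_id > 1000
  cutpoint <- sqrt(0.004 * 0.02)  # geometric midpoint
  accuracy <- mean((per$d_micro > cutpoint) == lab)
  expect_gt(accuracy, 0.9)
})

test_that("median per-trajectory micro D is unbiased across D values", {
  p <- track_filter_params(min_locs = 150)
  for (d in c(0.004, 0.01, 0.02)) {
    trk <- simulate_tracks(track_config(n_tracks = 60, d_true = d, dt_ms = 2,
                                        n_locs = 200, loc_sigma = 0,
                                        rng_seed = round(1e4 * d)))
    per <- fit_trajectories(build_trajectories(trk$localizations, p)$trajectories, p)
    ci <- bootstrap_median_ci(per$d_micro, n_boot = 2000, seed = 1)
    expect_gt(d, ci$ci_lo - 0.1 * d)
    expect_lt(d, ci$ci_hi + 0.1 * d)
  }
})

test_that("confinement orders macro below micro", {
  p <- track_filter_params(min_locs = 150)
  conf <- simulate_tracks(track_config(n_tracks = 60, d_true = 0.02, dt_ms = 2,
                                       n_locs = 400, loc_sigma = 0,
                                       corral_radius = 100,
                                       z_confinement_sd = 40, rng_seed = 71))
  ens <- ensemble_msd(build_trajectories(conf$localizations, p)$trajectories, p)
  expect_lt(ens$fit_macro$d, ens$fit_micro$d)
})
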