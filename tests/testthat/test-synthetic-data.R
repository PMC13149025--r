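test_that("scene generator: counting, determinism, degenerate noise", {
  cfg <- scene_config(n_trimers = 10, label_efficiency = 1,
                      background_density = 0, rng_seed = 11)
  sc <- simulate_scene(cfg)
  expect_equal(nrow(sc$truth$vertices), 30L)
  expect_true(all(sc$truth$vertices$labelled))

  sc2 <- simulate_scene(cfg)
  expect_identical(sc$localizations, sc2$localizations)
  expect_identical(sc$truth, sc2$truth)

  deg <- simulate_scene(scene_config(n_trimers = 5, side_mean = 20,
                                     side_sd = 0, vertex_sigma_xy = 0,
                                     vertex_sigma_z = 0,
                                     background_density = 0, rng_seed = 2))
  v <- deg$truth$vertices
  for (id in unique(v$trimer_id)) {
    tri <- as.matrix(v[v$trimer_id == id, c("x", "y", "z")])
    sides <- as.numeric(dist(tri))
    expect_equal(sides, rep(20, 3), tolerance = 1e-12)
  }
})

test_that("scene generator rejects invalid configs", {
  expect_error(scene_config(side_mean = -1), "side_mean")
  expect_error(scene_config(label_efficiency = 1.2), "label_efficiency")
  expect_error(scene_config(background_density = NA), "background_density")
  expect_error(scene_config(vertex_sigma_xy = -3), "vertex_sigma_xy")
})

test_that("ground-truth side lengths are Normal(side_mean, side_sd)", {
  sc <- simulate_scene(scene_config(n_trimers = 1000, side_mean = 20,
                                    side_sd = 1.5, traces_per_vertex_mean = 0,
                                    background_density = 0, field_size = 60,
                                    rng_seed = 5))
  ks <- suppressWarnings(
    stats::ks.test(sc$truth$trimers$side, "pnorm", 20, 1.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("scene EFO distribution has single- and two-emitter modes", {
  sc <- simulate_scene(scene_config(n_trimers = 60, multi_emitter_fraction = 0.5,
                                    background_density = 0, rng_seed = 9))
  efo <- sc$localizations$efo
  # the two generating modes at 75 and 150 kHz must both be populated
  expect_gt(mean(efo < 110e3), 0.3)
  expect_gt(mean(efo > 110e3), 0.3)
})

test_that("track generator: degenerate, determinism, increment variance", {
  still <- simulate_tracks(track_config(n_tracks = 3, d_true = 0,
                                        loc_sigma = 0, n_locs = 50,
                                        rng_seed = 4))
  one <- still$localizations[still$localizations$trace_id == 1, ]
  expect_equal(diff(range(one$x)), 0)
  expect_equal(diff(range(one$z)), 0)

  cfg <- track_config(n_tracks = 5, rng_seed = 8)
  expect_identical(simulate_tracks(cfg)$localizations,
                   simulate_tracks(cfg)$localizations)
  expect_error(track_config(d_true = -0.01), "d_true")

  # per-axis increment variance within 2% of 2 D dt over 1e5 increments
  d <- 0.01; dt_ms <- 2
  trk <- simulate_tracks(track_config(n_tracks = 201, d_true = d,
                                      dt_ms = dt_ms, n_locs = 501,
                                      loc_sigma = 0, rng_seed = 13))
  inc <- unlist(lapply(split(trk$localizations$x, trk$localizations$trace_id),
                       diff), use.names = FALSE)
  expect_gt(length(inc), 1e5)
  expect_equal(var(inc), 2 * d * 1e6 * dt_ms / 1000, tolerance = 0.02)
})

test_that("track ensemble MSD matches 6 D tau and static-error offset", {
  # closed form 6 D tau at lag 50 ms vs sample mean (scaled to 300 tracks
  # to stay in budget; the 3-MC-s.e. bound adapts to n)
  d <- 0.01
  trk <- simulate_tracks(track_config(n_tracks = 300, d_true = d, dt_ms = 2,
                                      n_locs = 500, loc_sigma = 0,
                                      rng_seed = 21))
  sp <- split(trk$localizations, trk$localizations$trace_id)
  r2 <- unlist(lapply(sp, function(p) {
    k <- 25  # 25 steps x 2 ms = 50 ms lag
    i <- seq_len(nrow(p) - k)
    (p$x[i + k] - p$x[i])^2 + (p$y[i + k] - p$y[i])^2 + (p$z[i + k] - p$z[i])^2
  }), use.names = FALSE) / 1e6  # um^2
  expected <- 6 * d * 0.05
  se <- sd(r2) / sqrt(length(unique(trk$localizations$trace_id)) * 19)
  # displacement pairs overlap heavily; effective n ~ tracks * (500/25)
  expect_lt(abs(mean(r2) - expected), 3 * se)

  # static localization error adds ~6 sigma^2 to the MSD intercept
  sigma <- 20
  trk2 <- simulate_tracks(track_config(n_tracks = 150, d_true = d, dt_ms = 2,
                                       n_locs = 400, loc_sigma = sigma,
                                       rng_seed = 22))
  built <- build_trajectories(trk2$localizations,
                              track_filter_params(min_locs = 100))
  ens <- ensemble_msd(built$trajectories,
                      track_filter_params(min_locs = 100, lag_bin_width = 2))
  fit <- fit_diffusion(ens$curve, window = c(1, 30), intercept = TRUE)
  expect_equal(fit$intercept_um2, 6 * sigma^2 / 1e6, tolerance = 0.25)
})

test_that("track gaps advance the clock and keep timestamps monotone", {
  trk <- simulate_tracks(track_config(n_tracks = 10, gap_prob = 0.2,
                                      gap_len_ms = 25, dt_ms = 2,
                                      n_locs = 100, rng_seed = 6))
  for (p in split(trk$localizations, trk$localizations$trace_id)) {
    dt <- diff(p$t) * 1000
    expect_true(all(dt > 0))
    expect_true(any(dt > 18))  # gaps present at this rate
  }
})

test_that("two-channel image generator renders spots and honours coloc", {
  spots <- data.frame(x = 40.5, y = 60.5, amplitude = 7, sigma_nm = 60)
  img <- simulate_two_channel_image(
    image_config(shape = c(100, 100), pixel_nm = 20, spots_ch1 = spots,
                 noise_sd = 0, rng_seed = 1))
  peak <- which(img$ch1 == max(img$ch1), arr.ind = TRUE)
  expect_equal(max(img$ch1), 7, tolerance = 0.05)
  expect_equal(unname(peak[1, ]), c(60, 40), tolerance = 1)

  ch1 <- data.frame(x = c(20, 70, 40), y = c(20, 30, 80),
                    amplitude = 5, sigma_nm = 60)
  ch2 <- data.frame(x = c(55, 25, 90), y = c(45, 65, 15),
                    amplitude = 4, sigma_nm = 60)
  full <- simulate_two_channel_image(
    image_config(shape = c(100, 100), spots_ch1 = ch1, spots_ch2 = ch2,
                 coloc_fraction = 1, rng_seed = 3))
  expect_true(all(paste(full$spots$ch2$x, full$spots$ch2$y) %in%
                  paste(ch1$x, ch1$y)))

  expect_error(image_config(shape = c(50, 50),
                            spots_ch1 = data.frame(x = 60, y = 10,
                                                   amplitude = 1,
                                                   sigma_nm = 30)),
               "outside")
})
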