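test_that("two-step DBSCAN: tight blob is one cluster, singleton is noise", {
  set.seed(1)
  blob <- loc_table(x = rnorm(10, 0, 1), y = rnorm(10, 0, 1),
                    z = rnorm(10, 0, 1))
  lab <- cluster_localizations(blob)
  expect_equal(nrow(lab), 10L)
  expect_equal(unique(lab$cluster), 1L)

  lone <- loc_table(x = c(rnorm(10, 0, 1), 500),
                    y = c(rnorm(10, 0, 1), 500),
                    z = c(rnorm(10, 0, 1), 0))
  lab2 <- cluster_localizations(lone)
  expect_equal(nrow(lab2), 10L)  # the isolated point was removed as noise
  expect_false(any(lab2$x > 400))

  empty <- cluster_localizations(loc_table(x = numeric(0), y = numeric(0),
                                           z = numeric(0),
                                           trace_id = integer(0),
                                           t = numeric(0), efo = numeric(0),
                                           valid = logical(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("dbscan3d matches the brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    # mixture of blobs and uniform background, random parameters
    n_blob <- sample(3:6, 1)
    pts <- rbind(
      do.call(rbind, lapply(seq_len(n_blob), function(k) {
        c0 <- runif(3, 0, 200)
        cbind(rnorm(25, c0[1], 4), rnorm(25, c0[2], 4), rnorm(25, c0[3], 4))
      })),
      matrix(runif(3 * (200 - 25 * n_blob), 0, 200), ncol = 3))
    eps <- runif(1, 5, 15); minpts <- sample(3:8, 1)
    expect_identical(canonical_labels(dbscan3d(pts, eps, minpts)),
                     canonical_labels(dbscan_oracle(pts, eps, minpts)))
  }
})

test_that("step-1 + step-2 equals step 2 alone on the de-noised set", {
  set.seed(7)
  sc <- simulate_scene(scene_config(n_trimers = 10, rng_seed = 19))
  tab <- filter_traces(sc$localizations)$table
  lab <- cluster_localizations(tab)
  direct <- dbscan3d(as.matrix(lab[, c("x", "y", "z")]), 7, 5)
  expect_identical(canonical_labels(lab$cluster), canonical_labels(direct))
})

test_that("GMM position fitting: exact point, two blobs, error filter", {
  # all localizations at exactly one point -> that point, error 0
  one <- loc_table(x = rep(5, 8), y = rep(-3, 8), z = rep(1, 8))
  one$cluster <- 1L
  fit <- fit_positions(one)
  expect_equal(fit$positions[, c("x", "y", "z")],
               data.frame(x = 5, y = -3, z = 1), tolerance = 1e-9)
  expect_equal(fit$positions$error, 0)

  # two clusters 50 nm apart, sigma 3, n = 100: means within 1 nm of truth
  set.seed(23)
  pts <- loc_table(
    x = c(rnorm(100, 0, 3), rnorm(100, 50, 3)),
    y = c(rnorm(100, 0, 3), rnorm(100, 0, 3)),
    z = c(rnorm(100, 0, 3), rnorm(100, 0, 3)))
  lab <- cluster_localizations(pts)
  fit2 <- fit_positions(lab)
  expect_equal(nrow(fit2$positions), 2L)
  mu <- fit2$positions[order(fit2$positions$x), c("x", "y", "z")]
  expect_lt(sqrt(sum((unlist(mu[1, ]) - c(0, 0, 0))^2)), 1)
  expect_lt(sqrt(sum((unlist(mu[2, ]) - c(50, 0, 0))^2)), 1)
  expect_true(all(fit2$positions$n_locs >= 5))

  # member s.d. 12 nm > 10 nm threshold: dropped and logged
  set.seed(24)
  wide <- loc_table(x = rnorm(60, 0, 12), y = rnorm(60, 0, 12),
                    z = rnorm(60, 0, 12))
  wide$cluster <- 1L
  fit3 <- fit_positions(wide)
  expect_equal(nrow(fit3$positions), 0L)
  expect_equal(fit3$log$dropped_error, 1L)
})

test_that("EM log-likelihood is monotone (debug assertion active)", {
  set.seed(31)
  pts <- loc_table(
    x = c(rnorm(60, 0, 3), rnorm(60, 14, 3), rnorm(60, 28, 3)),
    y = rnorm(180, 0, 3), z = rnorm(180, 0, 3))
  lab <- cluster_localizations(pts, cluster_params(eps2 = 7))
  expect_no_error(fit_positions(lab, debug = TRUE))
})

test_that("position recovery in the sparse operating regime", {
  # The clustering stage assumes protomer clouds resolvable at eps2 = 7 nm:
  # sigma 3 nm and ~15 localizations per vertex. At higher densities cloud
  # bridging produces midpoint artifacts (see the methods vignette).
  sc <- simulate_scene(scene_config(n_trimers = 40, side_mean = 20,
                                    side_sd = 1.5, vertex_sigma_xy = 3,
                                    vertex_sigma_z = 3,
                                    traces_per_vertex_mean = 1,
                                    locs_per_vertex_mean = 15,
                                    background_density = 0, rng_seed = 41))
  tab <- filter_traces(sc$localizations)$table
  pos <- fit_positions(cluster_localizations(tab))$positions
  expect_gt(nrow(pos), 30)
  v <- sc$truth$vertices
  dmin <- vapply(seq_len(nrow(pos)), function(i)
    min(sqrt((v$x - pos$x[i])^2 + (v$y - pos$y[i])^2 +
             (v$z - pos$z[i])^2)), numeric(1))
  expect_gte(mean(dmin <= 3), 0.95)
})
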