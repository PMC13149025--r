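positions_df <- function(m) data.frame(x = m[, 1], y = m[, 2], z = m[, 3])

test_that("trimer identification accepts and rejects per the rules", {
  tri <- triangle_vertices(20)
  res <- identify_trimers(positions_df(tri))
  expect_equal(nrow(res$trimers), 1L)
  expect_equal(res$trimers$d_mean, 20, tolerance = 1e-9)

  # a pair 20 nm apart never forms a size-3 cluster
  pair <- positions_df(tri[1:2, , drop = FALSE])
  expect_equal(nrow(identify_trimers(pair)$trimers), 0L)

  # interloper within the isolation radius inflates the cluster: rejected
  crowd <- positions_df(rbind(tri, c(45, 0, 0)))
  res2 <- identify_trimers(crowd)
  expect_equal(nrow(res2$trimers), 0L)
  expect_true("size_not_3" %in% res2$rejections$reason)

  # one side below the 6 nm window: rejected as too close
  squeeze <- positions_df(rbind(c(0, 0, 0), c(4, 0, 0), c(10, 17, 0)))
  res3 <- identify_trimers(squeeze)
  expect_equal(nrow(res3$trimers), 0L)
  expect_equal(res3$rejections$reason, "pair_too_close")

  expect_equal(nrow(identify_trimers(positions_df(tri[0, ]))$trimers), 0L)
})

test_that("window bounds are open intervals", {
  # side exactly 6 nm must be rejected, side just inside accepted
  at_lo <- positions_df(triangle_vertices(6))
  expect_equal(nrow(identify_trimers(at_lo)$trimers), 0L)
  in_lo <- positions_df(triangle_vertices(6.01))
  expect_equal(nrow(identify_trimers(in_lo)$trimers), 1L)
})

test_that("interblade distances: mean, isometry invariance, summary", {
  v <- rbind(c(0, 0, 0), c(18, 0, 0), c(6, 19, 3))
  base <- identify_trimers(positions_df(v))$trimers
  d_ref <- unlist(base[, c("d12", "d13", "d23")])
  expect_equal(base$d_mean, mean(d_ref))

  set.seed(9)
  for (rep in 1:5) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
    shift <- runif(3, -1e4, 1e4)
    moved <- sweep(v %*% t(R), 2, shift, `+`)
    tri2 <- identify_trimers(positions_df(moved))$trimers
    expect_equal(sort(unlist(tri2[, c("d12", "d13", "d23")])),
                 sort(d_ref), tolerance = 1e-9)
  }

  # 18/20/22 triangle -> d_mean exactly 20
  a <- c(0, 0, 0); b <- c(18, 0, 0)
  # place c so |ac| = 20 and |bc| = 22
  cx <- (18^2 + 20^2 - 22^2) / (2 * 18)
  cc <- c(cx, sqrt(20^2 - cx^2), 0)
  tri3 <- identify_trimers(positions_df(rbind(a, b, cc)))$trimers
  expect_equal(tri3$d_mean, 20, tolerance = 1e-9)

  summ <- interblade_distances(tri3, n_boot = 200, seed = 1)
  expect_false(summ$summary$empty)
  expect_equal(summ$summary$n, 1L)
  expect_equal(summ$summary$median, 20, tolerance = 1e-9)
  expect_named(summ$distances,
               c("molecule_id", "d12", "d13", "d23", "d_mean"))

  empty <- interblade_distances(tri3[0, ])
  expect_true(empty$summary$empty)
})

test_that("measured distances vs brute-force noisy-distance Monte Carlo", {
  # positions carry error sigma_v; oracle simulates ||(a+e1)-(b+e2)|| with
  # sides drawn from the same Normal law
  sigma_v <- 1; side_mean <- 20; side_sd <- 1.5
  set.seed(11)
  n <- 400
  meas <- numeric(n)
  for (i in seq_len(n)) {
    v <- triangle_vertices(rnorm(1, side_mean, side_sd),
                           theta = runif(1, 0, 2 * pi)) +
         matrix(rnorm(9, 0, sigma_v), 3, 3)
    tri <- identify_trimers(positions_df(v))$trimers
    meas[i] <- if (nrow(tri) == 1) tri$d_mean else NA
  }
  meas <- meas[!is.na(meas)]

  oracle <- replicate(20000, {
    s <- rnorm(1, side_mean, side_sd)
    a <- c(0, 0, 0) + rnorm(3, 0, sigma_v)
    b <- c(s, 0, 0) + rnorm(3, 0, sigma_v)
    sqrt(sum((a - b)^2))
  })
  expect_equal(median(meas), median(oracle),
               tolerance = 3 * 1.25 * sd(oracle) / sqrt(length(meas)) /
                 median(oracle))

  # noise inflation: measured mean >= generating side mean
  expect_gte(mean(meas), side_mean - 0.05)
  expect_gte(mean(oracle), side_mean)
})

test_that("random in-plane channel orientation does not bias distances", {
  mk_scene <- function(rotate, seed) {
    set.seed(seed)
    d <- numeric(0)
    for (i in 1:250) {
      th <- if (rotate) runif(1, 0, 2 * pi) else 0
      v <- triangle_vertices(rnorm(1, 20, 1.5), theta = th) +
           matrix(rnorm(9, 0, 1), 3, 3)
      tri <- identify_trimers(positions_df(v))$trimers
      if (nrow(tri)) d <- c(d, tri$d_mean)
    }
    d
  }
  res <- ks_test(mk_scene(TRUE, 3), mk_scene(FALSE, 4))
  expect_gt(res$p_value, 0.01)
})

test_that("every accepted trimer satisfies all pairwise windows", {
  sc <- simulate_scene(scene_config(n_trimers = 30, rng_seed = 77))
  out <- analyze_structure(sc$localizations, pipeline_config(rng_seed = 77))
  tri <- out$trimers
  expect_gt(nrow(tri), 0)
  d <- as.matrix(tri[, c("d12", "d13", "d23")])
  expect_true(all(d > 6 & d < 60))
  expect_equal(tri$d_mean, unname(rowMeans(d)))
  # triangle inequality
  expect_true(all(d[, "d12"] < d[, "d13"] + d[, "d23"] + 1e-9))
})
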