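#' Configuration for synthetic MINFLUX tracking data
#'
#' Describes 3D Brownian trajectories of sparsely labelled single molecules
#' sampled at an irregular interval, with optional dark gaps, static
#' localization error, membrane z confinement and an xy reflecting corral.
#'
#' @param n_tracks number of trajectories.
#' @param d_true diffusion coefficient (um^2/s) generating the motion.
#' @param dt_ms nominal sampling interval (ms).
#' @param dt_jitter_ms Gaussian jitter s.d. of the interval (ms); intervals
#'   are floored at 10% of `dt_ms`.
#' @param n_locs localizations per track before gaps/truncation.
#' @param loc_sigma static localization error s.d. (nm), isotropic.
#' @param gap_prob probability per step of inserting a dark gap.
#' @param gap_len_ms length of an inserted gap (ms); the molecule keeps
#'   diffusing during the gap.
#' @param z_confinement_sd when > 0, z positions are resampled i.i.d.
#'   Gaussian with this s.d. (nm) about the membrane plane instead of
#'   following free Brownian motion.
#' @param corral_radius radius (nm) of a reflecting circular xy corral
#'   centred on the track origin; `Inf` disables it. Needed to emulate
#'   cytoskeletal confinement (macroscopic < microscopic diffusion).
#' @param efo_mode_hz EFO mode (Hz) for the simulated dye.
#' @param efo_sdlog log-normal shape of the EFO distribution.
#' @param rng_seed integer seed.
#' @return object of class `track_config`.
#' @export
track_config <- function(n_tracks = 100, d_true = 0.01, dt_ms = 2,
                         dt_jitter_ms = 0, n_locs = 500, loc_sigma = 5,
                         gap_prob = 0, gap_len_ms = 25,
                         z_confinement_sd = 0, corral_radius = Inf,
                         efo_mode_hz = 75000, efo_sdlog = 0.25,
                         rng_seed = 1L) {
  check_scalar(n_tracks, "n_tracks", lo = 0, integerish = TRUE)
  check_scalar(d_true, "d_true", lo = 0)
  check_scalar(dt_ms, "dt_ms", lo = .Machine$double.eps)
  check_scalar(dt_jitter_ms, "dt_jitter_ms", lo = 0)
  check_scalar(n_locs, "n_locs", lo = 2, integerish = TRUE)
  check_scalar(loc_sigma, "loc_sigma", lo = 0)
  check_scalar(gap_prob, "gap_prob", lo = 0, hi = 1)
  check_scalar(gap_len_ms, "gap_len_ms", lo = 0)
  check_scalar(z_confinement_sd, "z_confinement_sd", lo = 0)
  if (!(is.numeric(corral_radius) && length(corral_radius) == 1L &&
        (is.infinite(corral_radius) || corral_radius > 0)))
    stop_mfx("'corral_radius' must be a positive number or Inf")
  check_scalar(efo_mode_hz, "efo_mode_hz", lo = 0)
  check_scalar(efo_sdlog, "efo_sdlog", lo = 0)
  check_scalar(rng_seed, "rng_seed", integerish = TRUE)
  structure(as.list(environment()), class = "track_config")
}

#' Simulate single-molecule MINFLUX trajectories
#'
#' Per step, 3D Gaussian increments with per-axis variance `2 * d_true * dt`
#' (dt the actual elapsed time, including dark gaps), optional i.i.d. z
#' confinement, optional xy reflecting corral, then static localization
#' noise. Timestamps are strictly increasing.
#'
#' @param config a [track_config()].
#' @return list of class `mfx_tracks`: `localizations` (canonical table,
#'   one `trace_id` per track) and `truth` (`track_id`, `d_true`), plus the
#'   config.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "track_config"))
  with_seed(config$rng_seed, {
    cf <- config
    mu_efo <- log(cf$efo_mode_hz) + cf$efo_sdlog^2
    rows <- vector("list", cf$n_tracks)
    for (i in seq_len(cf$n_tracks)) {
      n <- cf$n_locs
      dt <- rep(cf$dt_ms, n - 1)
      if (cf$dt_jitter_ms > 0)
        dt <- pmax(dt + rnorm(n - 1, 0, cf$dt_jitter_ms), 0.1 * cf$dt_ms)
      if (cf$gap_prob > 0)
        dt <- dt + cf$gap_len_ms * (runif(n - 1) < cf$gap_prob)
      t <- c(0, cumsum(dt)) / 1000  # seconds
      # per-axis increment sd in nm: var = 2 D dt ; D um^2/s -> nm^2/s = D*1e6
      sd_inc <- sqrt(2 * cf$d_true * 1e6 * dt / 1000)
      x0 <- runif(1, 0, 5000); y0 <- runif(1, 0, 5000)
      x <- x0 + c(0, cumsum(rnorm(n - 1, 0, sd_inc)))
      y <- y0 + c(0, cumsum(rnorm(n - 1, 0, sd_inc)))
      if (is.finite(cf$corral_radius))
        xy <- reflect_corral(x, y, x0, y0, cf$corral_radius)
      else xy <- list(x = x, y = y)
      z <- if (cf$z_confinement_sd > 0)
        rnorm(n, 0, cf$z_confinement_sd)
      else c(0, cumsum(rnorm(n - 1, 0, sd_inc)))
      rows[[i]] <- make_loc_table(
        trace_id = i, t = t,
        x = xy$x + rnorm(n, 0, cf$loc_sigma),
        y = xy$y + rnorm(n, 0, cf$loc_sigma),
        z = z + rnorm(n, 0, cf$loc_sigma),
        efo = rlnorm(n, mu_efo, cf$efo_sdlog))
    }
    locs <- if (cf$n_tracks) do.call(rbind, rows) else
      make_loc_table(integer(0), numeric(0), numeric(0), numeric(0),
                     numeric(0), numeric(0), logical(0))
    attr(locs, "z_corrected") <- TRUE  # true coordinates, nothing to undo
    structure(list(
      localizations = locs,
      truth = data.frame(track_id = seq_len(cf$n_tracks),
                         d_true = rep(cf$d_true, cf$n_tracks)),
      config = config), class = "mfx_tracks")
  })
}

# Reflect a random walk into a circular corral of radius R about (x0, y0).
# Applied increment-wise so later steps start from the reflected position.
reflect_corral <- function(x, y, x0, y0, R) {
  n <- length(x)
  dx <- diff(x); dy <- diff(y)
  px <- x0; py <- y0
  ox <- numeric(n); oy <- numeric(n)
  ox[1] <- x0; oy[1] <- y0
  for (i in seq_len(n - 1)) {
    px <- px + dx[i]; py <- py + dy[i]
    r <- sqrt((px - x0)^2 + (py - y0)^2)
    if (r > R) {  # radial fold-back across the boundary
      scale <- (2 * R - r) / r
      px <- x0 + (px - x0) * scale
      py <- y0 + (py - y0) * scale
    }
    ox[i + 1] <- px; oy[i + 1] <- py
  }
  list(x = ox, y = oy)
}

#' @export
print.mfx_tracks <- function(x, ...) {
  cat(sprintf("MINFLUX synthetic tracks: %d tracks x %d localizations, D = %g um^2/s\n",
              x$config$n_tracks, x$config$n_locs, x$config$d_true))
  invisible(x)
}
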