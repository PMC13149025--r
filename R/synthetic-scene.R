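#' Configuration for a synthetic DNA-PAINT MINFLUX scene
#'
#' Describes a field of trimeric channels sitting in a flat membrane, each
#' labelled at up to three equivalent blade positions. Labelled vertices emit
#' bursts ("traces") of localizations with isotropic Gaussian localization
#' noise; the per-localization emission-frequency readout (EFO) is drawn
#' from a log-normal around a single-emitter mode, with a configurable
#' fraction of traces at twice that mode (two active dyes). Background
#' localizations are uniform in the field.
#'
#' @param n_trimers number of trimers placed uniformly in the field.
#' @param side_mean,side_sd mean and s.d. (nm) of the Normal distribution of
#'   the equilateral triangle side (interblade distance at truth level).
#' @param vertex_sigma_xy,vertex_sigma_z isotropic localization noise (nm)
#'   in xy and z. Defaults (3 and 4 nm) are plausible DNA-PAINT MINFLUX
#'   precisions, exposed here because the true values are instrument
#'   dependent.
#' @param locs_per_vertex_mean Poisson mean localizations per trace.
#' @param traces_per_vertex_mean Poisson mean binding events per labelled
#'   vertex.
#' @param label_efficiency probability a vertex carries a docking strand.
#' @param background_density spurious localizations per square micrometre.
#' @param multi_emitter_fraction probability a trace reflects two active
#'   emitters (EFO mode doubled).
#' @param efo_mode_hz single-emitter EFO mode (Hz); two-emitter traces use
#'   exactly twice this value.
#' @param efo_sdlog log-normal shape parameter of the EFO distribution.
#' @param membrane_z z position of the membrane plane (nm).
#' @param field_size side of the square field (micrometres).
#' @param tilt_sd out-of-plane tilt s.d. (radians); 0 keeps trimers flat in
#'   the membrane.
#' @param rng_seed integer seed making the scene reproducible.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(n_trimers = 50, side_mean = 20, side_sd = 1.5,
                         vertex_sigma_xy = 3, vertex_sigma_z = 4,
                         locs_per_vertex_mean = 20, traces_per_vertex_mean = 4,
                         label_efficiency = 1, background_density = 0.5,
                         multi_emitter_fraction = 0.1, efo_mode_hz = 75000,
                         efo_sdlog = 0.25, membrane_z = 0, field_size = 20,
                         tilt_sd = 0, rng_seed = 1L) {
  check_scalar(n_trimers, "n_trimers", lo = 0, integerish = TRUE)
  check_scalar(side_mean, "side_mean", lo = .Machine$double.eps)
  check_scalar(side_sd, "side_sd", lo = 0)
  check_scalar(vertex_sigma_xy, "vertex_sigma_xy", lo = 0)
  check_scalar(vertex_sigma_z, "vertex_sigma_z", lo = 0)
  check_scalar(locs_per_vertex_mean, "locs_per_vertex_mean", lo = 0)
  check_scalar(traces_per_vertex_mean, "traces_per_vertex_mean", lo = 0)
  check_scalar(label_efficiency, "label_efficiency", lo = 0, hi = 1)
  check_scalar(background_density, "background_density", lo = 0)
  check_scalar(multi_emitter_fraction, "multi_emitter_fraction", lo = 0, hi = 1)
  check_scalar(efo_mode_hz, "efo_mode_hz", lo = 0)
  check_scalar(efo_sdlog, "efo_sdlog", lo = 0)
  check_scalar(membrane_z, "membrane_z")
  check_scalar(field_size, "field_size", lo = .Machine$double.eps)
  check_scalar(tilt_sd, "tilt_sd", lo = 0)
  check_scalar(rng_seed, "rng_seed", integerish = TRUE)
  structure(as.list(environment()), class = "scene_config")
}

#' Simulate a structural MINFLUX scene
#'
#' Generates a localization table plus ground truth for a field of trimers.
#' Each trimer is an equilateral triangle (side drawn from
#' `Normal(side_mean, side_sd)`) with uniform in-plane rotation at
#' `z = membrane_z`; each labelled vertex emits a Poisson number of traces,
#' each trace a Poisson number of localizations displaced by isotropic
#' Gaussian noise. Fully reproducible given `rng_seed`.
#'
#' @param config a [scene_config()].
#' @return list of class `mfx_scene` with elements
#'   \describe{
#'     \item{localizations}{canonical localization table
#'       (`trace_id, t, x, y, z, efo, valid`).}
#'     \item{truth}{list with `trimers` (id, centre, side, rotation),
#'       `vertices` (trimer id, vertex id, position, labelled flag) and
#'       `origin` (per-trace vertex id, `NA` for background).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$rng_seed, {
    cf <- config
    field_nm <- cf$field_size * 1000

    n <- cf$n_trimers
    centres <- cbind(runif(n, 0, field_nm), runif(n, 0, field_nm))
    sides <- rnorm(n, cf$side_mean, cf$side_sd)
    sides <- pmax(sides, 0.01 * cf$side_mean)  # guard absurd tails
    theta0 <- runif(n, 0, 2 * pi)

    # Vertex coordinates: equilateral triangle, circumradius side/sqrt(3).
    verts <- vector("list", max(n, 0))
    for (i in seq_len(n)) {
      ang <- theta0[i] + c(0, 2, 4) * pi / 3
      R <- sides[i] / sqrt(3)
      v <- cbind(centres[i, 1] + R * cos(ang),
                 centres[i, 2] + R * sin(ang),
                 rep(cf$membrane_z, 3))
      if (cf$tilt_sd > 0) {
        tilt <- rnorm(1, 0, cf$tilt_sd)
        axis_ang <- runif(1, 0, 2 * pi)
        v <- tilt_triangle(v, centres[i, ], tilt, axis_ang, cf$membrane_z)
      }
      verts[[i]] <- v
    }
    vertices <- if (n) do.call(rbind, verts) else matrix(numeric(0), ncol = 3)
    vtab <- data.frame(
      trimer_id = rep(seq_len(n), each = 3)[seq_len(3 * n)],
      vertex_id = seq_len(3 * n),
      x = vertices[, 1], y = vertices[, 2], z = vertices[, 3],
      labelled = FALSE)
    vtab$labelled <- runif(nrow(vtab)) < cf$label_efficiency

    # Emission traces per labelled vertex.
    mu_single <- log(cf$efo_mode_hz) + cf$efo_sdlog^2  # log-normal mode -> meanlog
    rows <- list(); origin <- list(); trace_counter <- 0L
    for (k in seq_len(nrow(vtab))) {
      if (!vtab$labelled[k]) next
      n_tr <- rpois(1, cf$traces_per_vertex_mean)
      if (n_tr == 0) next
      for (j in seq_len(n_tr)) {
        n_l <- rpois(1, cf$locs_per_vertex_mean)
        if (n_l == 0) next
        trace_counter <- trace_counter + 1L
        two <- runif(1) < cf$multi_emitter_fraction
        mu <- mu_single + if (two) log(2) else 0
        t0 <- runif(1, 0, 3600)
        rows[[length(rows) + 1L]] <- make_loc_table(
          trace_id = trace_counter,
          t = t0 + 0.001 * seq_len(n_l),
          x = vtab$x[k] + rnorm(n_l, 0, cf$vertex_sigma_xy),
          y = vtab$y[k] + rnorm(n_l, 0, cf$vertex_sigma_xy),
          z = vtab$z[k] + rnorm(n_l, 0, cf$vertex_sigma_z),
          efo = rlnorm(n_l, mu, cf$efo_sdlog))
        origin[[length(origin) + 1L]] <-
          data.frame(trace_id = trace_counter, vertex_id = vtab$vertex_id[k])
      }
    }

    # Background: isolated spurious localizations, broad EFO.
    n_bg <- rpois(1, cf$background_density * cf$field_size^2)
    if (n_bg > 0) {
      rows[[length(rows) + 1L]] <- make_loc_table(
        trace_id = trace_counter + seq_len(n_bg),
        t = runif(n_bg, 0, 3600),
        x = runif(n_bg, 0, field_nm),
        y = runif(n_bg, 0, field_nm),
        z = cf$membrane_z + runif(n_bg, -150, 150),
        efo = rlnorm(n_bg, mu_single, 0.6))
      origin[[length(origin) + 1L]] <-
        data.frame(trace_id = trace_counter + seq_len(n_bg),
                   vertex_id = NA_integer_)
    }

    locs <- if (length(rows)) do.call(rbind, rows) else
      make_loc_table(integer(0), numeric(0), numeric(0), numeric(0),
                     numeric(0), numeric(0), logical(0))
    locs <- locs[order(locs$trace_id, locs$t), , drop = FALSE]
    rownames(locs) <- NULL
    # synthetic coordinates are true positions: no refractive-index
    # distortion to undo, so mark the table as already z-corrected
    attr(locs, "z_corrected") <- TRUE

    structure(list(
      localizations = locs,
      truth = list(
        trimers = data.frame(trimer_id = seq_len(n),
                             cx = centres[, 1], cy = centres[, 2],
                             cz = rep(cf$membrane_z, n),
                             side = sides, theta = theta0),
        vertices = vtab,
        origin = if (length(origin)) do.call(rbind, origin) else
          data.frame(trace_id = integer(0), vertex_id = integer(0))),
      config = config), class = "mfx_scene")
  })
}

# Rotate triangle vertices out of the membrane plane about an in-plane axis
# through the centre.
tilt_triangle <- function(v, centre, tilt, axis_ang, z0) {
  a <- c(cos(axis_ang), sin(axis_ang), 0)
  p <- sweep(v, 2, c(centre, z0))
  ct <- cos(tilt); st <- sin(tilt)
  rot <- function(u) {
    u * ct + pracma_cross(a, u) * st + a * sum(a * u) * (1 - ct)
  }
  out <- t(apply(p, 1, rot))
  sweep(out, 2, c(centre, z0), `+`)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.mfx_scene <- function(x, ...) {
  cat(sprintf("MINFLUX synthetic scene: %d trimers, %d localizations (%d traces)\n",
              nrow(x$truth$trimers), nrow(x$localizations),
              length(unique(x$localizations$trace_id))))
  invisible(x)
}
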