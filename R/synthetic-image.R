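#' Configuration for a synthetic two-channel image
#'
#' Fixture generator for the STED colocalization branch: isotropic Gaussian
#' spots rendered on two channels with Gaussian read noise.
#'
#' @param shape image size, `c(rows, cols)` pixels.
#' @param pixel_nm pixel size in nm (STED default 20 nm/px).
#' @param spots_ch1,spots_ch2 data.frames with columns
#'   `x, y, amplitude, sigma_nm` (`x`/`y` in pixel units, 1-based, may be
#'   fractional).
#' @param coloc_fraction probability that a channel-2 spot is re-placed at
#'   the centre of a randomly chosen channel-1 spot.
#' @param noise_sd s.d. of additive Gaussian read noise (intensity units).
#' @param rng_seed integer seed.
#' @return object of class `image_config`.
#' @export
image_config <- function(shape = c(128, 128), pixel_nm = 20,
                         spots_ch1 = NULL, spots_ch2 = NULL,
                         coloc_fraction = 0, noise_sd = 0, rng_seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  check_scalar(pixel_nm, "pixel_nm", lo = .Machine$double.eps)
  check_scalar(coloc_fraction, "coloc_fraction", lo = 0, hi = 1)
  check_scalar(noise_sd, "noise_sd", lo = 0)
  check_scalar(rng_seed, "rng_seed", integerish = TRUE)
  for (nm in c("spots_ch1", "spots_ch2")) {
    s <- get(nm)
    if (is.null(s)) next
    if (!all(c("x", "y", "amplitude", "sigma_nm") %in% names(s)))
      stop_mfx("'%s' needs columns x, y, amplitude, sigma_nm", nm)
    if (any(s$sigma_nm <= 0)) stop_mfx("'%s': sigma_nm must be > 0", nm)
    if (any(s$x < 1 | s$x > shape[2] | s$y < 1 | s$y > shape[1]))
      stop_mfx("'%s': spot centres outside the field", nm)
  }
  structure(list(shape = as.integer(shape), pixel_nm = pixel_nm,
                 spots_ch1 = spots_ch1, spots_ch2 = spots_ch2,
                 coloc_fraction = coloc_fraction, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)), class = "image_config")
}

#' Simulate a two-channel spot image
#'
#' Renders each spot as a 2D isotropic Gaussian (sigma converted from nm to
#' pixels) and adds Gaussian read noise. With `coloc_fraction = 1` every
#' channel-2 spot centre coincides with a channel-1 spot centre.
#'
#' @param config an [image_config()].
#' @return list of class `mfx_image`: matrices `ch1`, `ch2` (rows = y) and
#'   `spots` (the ground-truth spot tables actually rendered).
#' @export
simulate_two_channel_image <- function(config) {
  stopifnot(inherits(config, "image_config"))
  with_seed(config$rng_seed, {
    cf <- config
    s2 <- cf$spots_ch2
    if (!is.null(s2) && nrow(s2) && !is.null(cf$spots_ch1) &&
        nrow(cf$spots_ch1) && cf$coloc_fraction > 0) {
      move <- runif(nrow(s2)) < cf$coloc_fraction
      pick <- sample.int(nrow(cf$spots_ch1), sum(move), replace = TRUE)
      s2$x[move] <- cf$spots_ch1$x[pick]
      s2$y[move] <- cf$spots_ch1$y[pick]
    }
    ch1 <- render_spots(cf$shape, cf$spots_ch1, cf$pixel_nm)
    ch2 <- render_spots(cf$shape, s2, cf$pixel_nm)
    if (cf$noise_sd > 0) {
      ch1 <- ch1 + matrix(rnorm(length(ch1), 0, cf$noise_sd), nrow(ch1))
      ch2 <- ch2 + matrix(rnorm(length(ch2), 0, cf$noise_sd), nrow(ch2))
    }
    structure(list(ch1 = ch1, ch2 = ch2,
                   spots = list(ch1 = cf$spots_ch1, ch2 = s2),
                   config = config), class = "mfx_image")
  })
}

render_spots <- function(shape, spots, pixel_nm) {
  img <- matrix(0, shape[1], shape[2])
  if (is.null(spots) || !nrow(spots)) return(img)
  ys <- seq_len(shape[1]); xs <- seq_len(shape[2])
  for (i in seq_len(nrow(spots))) {
    s_px <- spots$sigma_nm[i] / pixel_nm
    gy <- exp(-(ys - spots$y[i])^2 / (2 * s_px^2))
    gx <- exp(-(xs - spots$x[i])^2 / (2 * s_px^2))
    img <- img + spots$amplitude[i] * outer(gy, gx)
  }
  img
}
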