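#' ROI masking parameters for STED colocalization
#'
#' @param blur_radius Gaussian blur sigma in pixels applied to the
#'   reference channel before thresholding (default 10).
#' @param threshold fixed intensity threshold, applied identically to all
#'   images. No default: the value is chosen from the intensity histograms
#'   of a given dataset and must be supplied.
#' @param pixel_nm pixel size (nm, STED default 20).
#' @return object of class `roi_mask_params`.
#' @export
roi_mask_params <- function(blur_radius = 10, threshold, pixel_nm = 20) {
  check_scalar(blur_radius, "blur_radius", lo = 0)
  if (missing(threshold))
    stop_mfx("'threshold' has no default; choose it from the intensity histograms")
  check_scalar(threshold, "threshold")
  check_scalar(pixel_nm, "pixel_nm", lo = .Machine$double.eps)
  structure(list(blur_radius = blur_radius, threshold = threshold,
                 pixel_nm = pixel_nm), class = "roi_mask_params")
}

#' Separable Gaussian blur
#'
#' @param img numeric matrix.
#' @param sigma blur s.d. in pixels; 0 returns the input.
#' @return blurred matrix (replicate-padded borders).
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_1d <- function(m) {  # along rows (columns shift)
    nc <- ncol(m)
    out <- matrix(0, nrow(m), nc)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      cols <- pmin(pmax(seq_len(nc) + off, 1L), nc)  # replicate padding
      out <- out + k[j] * m[, cols, drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(img))))
}

#' Build a binary ROI mask from the reference channel
#'
#' Gaussian blur, fixed threshold, then 8-connected component labelling.
#' The mask is built only from the reference channel so the other channel
#' cannot bias ROI placement.
#'
#' @param reference_image 2D numeric matrix (reference channel).
#' @param params a [roi_mask_params()].
#' @return list: `mask` (logical matrix), `labels` (integer matrix, 0 =
#'   background), `n_roi`. An all-background image yields `n_roi = 0`
#'   without error.
#' @export
make_roi_mask <- function(reference_image, params) {
  stopifnot(inherits(params, "roi_mask_params"), is.matrix(reference_image))
  sm <- gaussian_blur(reference_image, params$blur_radius)
  mask <- sm > params$threshold
  labels <- label_components(mask)
  list(mask = mask, labels = labels, n_roi = max(labels))
}

#' 8-connected component labelling of a binary mask
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- ((p - 1L) %% nr) + 1L
      j <- ((p - 1L) %/% nr) + 1L
      for (dj in -1:1) for (di in -1:1) {
        if (di == 0L && dj == 0L) next
        ii <- i + di; jj <- j + dj
        if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
        q <- (jj - 1L) * nr + ii
        if (mask[q] && labels[q] == 0L) {
          labels[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Per-ROI intensity correlation between two channels
#'
#' Pearson's r and Spearman's rho (ranked Pearson, average ranks for ties)
#' over the pixels of each ROI. No additional intensity thresholds are
#' applied inside the ROIs. A constant channel within an ROI yields `NA`
#' coefficients with `undefined = TRUE`.
#'
#' @param image_a,image_b co-registered matrices of identical shape.
#' @param labels ROI label matrix from [make_roi_mask()] (or a logical
#'   mask, treated as a single ROI).
#' @return data.frame: `roi_id, n_pixels, pearson_r, spearman_rho,
#'   undefined`.
#' @export
coloc_correlation <- function(image_a, image_b, labels) {
  stopifnot(all(dim(image_a) == dim(image_b)))
  if (is.logical(labels)) labels <- label_components(labels)
  stopifnot(all(dim(labels) == dim(image_a)))
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (!length(ids))
    return(data.frame(roi_id = integer(0), n_pixels = integer(0),
                      pearson_r = numeric(0), spearman_rho = numeric(0),
                      undefined = logical(0)))
  do.call(rbind, lapply(ids, function(id) {
    sel <- labels == id
    a <- image_a[sel]; b <- image_b[sel]
    undef <- sd(a) == 0 || sd(b) == 0 || length(a) < 2
    data.frame(
      roi_id = id, n_pixels = sum(sel),
      pearson_r = if (undef) NA_real_ else stats::cor(a, b),
      spearman_rho = if (undef) NA_real_ else
        stats::cor(rank(a), rank(b)),
      undefined = undef)
  }))
}

#' FWHM of puncta by orthogonal Gaussian profile fits
#'
#' Local maxima above a prominence floor (default 3 x the robust noise
#' s.d., MAD-based, above the median) are fitted with 1D Gaussians (with
#' free offset) along x and y profiles through the peak;
#' `FWHM = 2 sqrt(2 ln 2) * sigma * pixel_nm`, averaged over the two axes.
#' Peaks whose profile fit explains less than `min_r2` of the variance are
#' dropped.
#'
#' @param image 2D numeric matrix.
#' @param params a [roi_mask_params()] (for `pixel_nm`).
#' @param prominence absolute intensity floor for peak detection; default
#'   `median(image) + 3 * mad(image)`.
#' @param half_width half-width (pixels) of the profile around the peak.
#' @param min_r2 minimum fit R^2.
#' @return data.frame: `x, y, fwhm_nm, r2` (one row per accepted peak).
#' @export
puncta_fwhm <- function(image, params, prominence = NULL, half_width = 8,
                        min_r2 = 0.5) {
  stopifnot(is.matrix(image))
  pixel_nm <- if (inherits(params, "roi_mask_params")) params$pixel_nm
              else check_scalar(params, "pixel_nm", lo = 1e-12)
  if (is.null(prominence))
    prominence <- median(image) + 3 * stats::mad(image)
  nr <- nrow(image); nc <- ncol(image)
  peaks <- list()
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    v <- image[i, j]
    if (v <= prominence) next
    nbhd <- image[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v < max(nbhd) || sum(nbhd == v) > 1) next  # strict 8-neighbour max
    peaks[[length(peaks) + 1L]] <- c(i, j)
  }
  out <- list()
  for (p in peaks) {
    i <- p[1]; j <- p[2]
    fit_x <- fit_profile(image[i, max(1, j - half_width):min(nc, j + half_width)])
    fit_y <- fit_profile(image[max(1, i - half_width):min(nr, i + half_width), j])
    if (is.null(fit_x) || is.null(fit_y)) next
    r2 <- min(fit_x$r2, fit_y$r2)
    if (r2 < min_r2) next
    sigma_px <- (fit_x$sigma + fit_y$sigma) / 2
    out[[length(out) + 1L]] <- data.frame(
      x = j, y = i, fwhm_nm = 2 * sqrt(2 * log(2)) * sigma_px * pixel_nm,
      r2 = r2)
  }
  if (!length(out))
    return(data.frame(x = integer(0), y = integer(0), fwhm_nm = numeric(0),
                      r2 = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# 1D Gaussian + offset fit of an intensity profile; NULL on failure.
fit_profile <- function(v) {
  n <- length(v)
  if (n < 5) return(NULL)
  u <- seq_len(n)
  b0 <- min(v); a0 <- max(v) - b0; c0 <- which.max(v)
  s0 <- max(1, sum(v - b0 > a0 / 2) / 2.3548)
  fit <- tryCatch(
    suppressWarnings(  # quality is gated on R^2, not on nls convergence
      nls(v ~ b + a * exp(-(u - cen)^2 / (2 * s^2)),
          start = list(b = b0, a = a0, cen = c0, s = s0),
          control = list(warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- coef(fit)
  ss_res <- sum((v - predict(fit))^2)
  ss_tot <- sum((v - mean(v))^2)
  if (ss_tot == 0) return(NULL)
  list(sigma = abs(co[["s"]]), r2 = 1 - ss_res / ss_tot)
}
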