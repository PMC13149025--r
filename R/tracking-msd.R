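#' Trajectory filtering and MSD parameters
#'
#' Defaults follow the fixed empirical thresholds used for 3D MINFLUX
#' tracking: per-trajectory mean EFO cutoff 130 kHz, truncation at the
#' first gap exceeding 18 ms, more than 200 localizations per trajectory,
#' microscopic fit window 5-50 ms, macroscopic window 50-350 ms, ensemble
#' MSD pooled into 50 linear lag bins between 0 and 350 ms.
#'
#' @param efo_max per-trajectory mean EFO cutoff (Hz).
#' @param max_gap maximum allowed time gap (ms) between successive
#'   localizations; a trajectory is truncated at the first larger gap.
#' @param min_locs trajectories must have strictly more localizations.
#' @param micro_window,macro_window lag windows (ms) for the microscopic and
#'   macroscopic diffusion fits.
#' @param ensemble_bins number of linearly spaced lag bins.
#' @param ensemble_tmax maximum lag (ms).
#' @param lag_bin_width per-trajectory lag bin width (ms); the default
#'   equals `ensemble_tmax / ensemble_bins` so per-trajectory and ensemble
#'   curves share a binning.
#' @return object of class `track_filter_params`.
#' @export
track_filter_params <- function(efo_max = 130000, max_gap = 18,
                                min_locs = 200, micro_window = c(5, 50),
                                macro_window = c(50, 350),
                                ensemble_bins = 50, ensemble_tmax = 350,
                                lag_bin_width = ensemble_tmax / ensemble_bins) {
  check_scalar(efo_max, "efo_max", lo = .Machine$double.eps)
  check_scalar(max_gap, "max_gap", lo = .Machine$double.eps)
  check_scalar(min_locs, "min_locs", lo = 1, integerish = TRUE)
  stopifnot(length(micro_window) == 2, length(macro_window) == 2,
            micro_window[1] < micro_window[2],
            macro_window[1] < macro_window[2],
            micro_window[2] <= macro_window[1])
  check_scalar(ensemble_bins, "ensemble_bins", lo = 2, integerish = TRUE)
  check_scalar(ensemble_tmax, "ensemble_tmax", lo = .Machine$double.eps)
  check_scalar(lag_bin_width, "lag_bin_width", lo = .Machine$double.eps)
  structure(list(efo_max = efo_max, max_gap = max_gap,
                 min_locs = as.integer(min_locs),
                 micro_window = micro_window, macro_window = macro_window,
                 ensemble_bins = as.integer(ensemble_bins),
                 ensemble_tmax = ensemble_tmax,
                 lag_bin_width = lag_bin_width),
            class = "track_filter_params")
}

#' Build gap-truncated single-molecule trajectories
#'
#' Localizations are grouped by trace id, sorted by time, truncated at the
#' first gap exceeding `max_gap` (the post-gap remainder is discarded, so
#' positions are never linked across long dark periods), and trajectories
#' with mean EFO above `efo_max` or at most `min_locs` localizations are
#' dropped.
#'
#' @param table tracking-mode localization table (z-corrected upstream).
#' @param params a [track_filter_params()].
#' @return list with `trajectories` (list of data.frames `t, x, y, z, efo`
#'   with attributes `track_id`, `truncated`) and `log` (filter counts).
#' @export
build_trajectories <- function(table, params = track_filter_params()) {
  stopifnot(inherits(params, "track_filter_params"))
  log <- list(traces_in = length(unique(table$trace_id)),
              truncated = 0L, dropped_efo = 0L, dropped_short = 0L)
  out <- list()
  for (piece in split(table, table$trace_id)) {
    piece <- piece[order(piece$t), , drop = FALSE]
    gaps <- diff(piece$t) * 1000  # ms
    cut <- which(gaps > params$max_gap)
    truncated <- length(cut) > 0
    if (truncated) {
      piece <- piece[seq_len(cut[1]), , drop = FALSE]
      log$truncated <- log$truncated + 1L
    }
    if (mean(piece$efo) > params$efo_max) {
      log$dropped_efo <- log$dropped_efo + 1L
      next
    }
    if (nrow(piece) <= params$min_locs) {
      log$dropped_short <- log$dropped_short + 1L
      next
    }
    traj <- piece[, c("t", "x", "y", "z", "efo")]
    rownames(traj) <- NULL
    attr(traj, "track_id") <- piece$trace_id[1]
    attr(traj, "truncated") <- truncated
    out[[length(out) + 1L]] <- traj
  }
  log$trajectories_out <- length(out)
  list(trajectories = out, log = log)
}

#' Time-averaged MSD of one trajectory
#'
#' All ordered localization pairs (i < j) with time difference at most
#' `ensemble_tmax` contribute their squared 3D displacement to the lag bin
#' containing the difference (bins of `lag_bin_width` from 0). The curve
#' reports, per populated bin, the pair-count-weighted mean actual lag (the
#' bin abscissa; using the nominal bin centre would bias fits when sampling
#' is regular), the mean squared displacement, and the pair count used as
#' fit weight.
#'
#' @param traj one trajectory data.frame (`t` seconds, `x/y/z` nm).
#' @param params a [track_filter_params()].
#' @return data.frame of class `mfx_msd`: `lag_ms, msd_um2, n_pairs`; zero
#'   rows (attribute `empty`) when no pair falls in any bin.
#' @export
compute_msd <- function(traj, params = track_filter_params()) {
  stopifnot(nrow(traj) >= 2)
  n <- nrow(traj)
  t_ms <- traj$t * 1000
  # pairs (i, i+k) for each forward offset k, kept while any pair at that
  # offset is still inside the lag window (timestamps are sorted)
  lag_list <- list(); sq_list <- list()
  for (k in seq_len(n - 1)) {
    i <- seq_len(n - k)
    dt <- t_ms[i + k] - t_ms[i]
    keep <- dt > 0 & dt <= params$ensemble_tmax
    if (!any(keep)) {
      if (min(dt) > params$ensemble_tmax) break
      next
    }
    i <- i[keep]
    lag_list[[k]] <- dt[keep]
    sq_list[[k]] <- (traj$x[i + k] - traj$x[i])^2 +
                    (traj$y[i + k] - traj$y[i])^2 +
                    (traj$z[i + k] - traj$z[i])^2   # nm^2
  }
  lag <- unlist(lag_list, use.names = FALSE)
  if (!length(lag)) {
    out <- data.frame(lag_ms = numeric(0), msd_um2 = numeric(0),
                      n_pairs = integer(0))
    attr(out, "empty") <- TRUE
    class(out) <- c("mfx_msd", "data.frame")
    return(out)
  }
  sq <- unlist(sq_list, use.names = FALSE)
  # round the edge ratio so lags sitting exactly on a bin boundary do not
  # leak into the next bin through floating-point noise
  bin <- pmax(1L, pmin(ceiling(round(lag / params$lag_bin_width, 9)),
                       ceiling(params$ensemble_tmax / params$lag_bin_width)))
  n_pairs <- tapply(sq, bin, length)
  out <- data.frame(
    bin = as.integer(names(n_pairs)),
    lag_ms = as.numeric(tapply(lag, bin, mean)),
    msd_um2 = as.numeric(tapply(sq, bin, mean)) / 1e6,
    n_pairs = as.integer(n_pairs))
  out <- out[order(out$bin), c("bin", "lag_ms", "msd_um2", "n_pairs")]
  rownames(out) <- NULL
  attr(out, "empty") <- FALSE
  class(out) <- c("mfx_msd", "data.frame")
  out
}

#' Weighted zero-intercept diffusion fit
#'
#' Weighted least squares of `MSD(tau) = 6 D tau` through the origin over
#' the lag bins inside `window`, with pair counts as weights. With
#' `intercept = TRUE` a free offset is added (static localization error
#' diagnostic; off by default to match the stated model).
#'
#' @param curve an MSD curve from [compute_msd()] or [ensemble_msd()].
#' @param window `c(lo, hi)` lag window in ms (closed interval on the bin
#'   abscissa).
#' @param intercept fit a free intercept as well.
#' @return list of class `mfx_diffusion_fit`: `d` (um^2/s), `window`,
#'   `n_lags`, `intercept_um2`, `residual_rms`; if fewer than two populated
#'   bins fall in the window the fit is refused (`d = NA`, `reason`).
#' @export
fit_diffusion <- function(curve, window = c(5, 50), intercept = FALSE) {
  stopifnot(length(window) == 2, window[1] < window[2])
  use <- curve$lag_ms >= window[1] & curve$lag_ms <= window[2] &
         curve$n_pairs >= 1
  pts <- curve[use, , drop = FALSE]
  if (nrow(pts) < 2)
    return(structure(list(d = NA_real_, window = window, n_lags = nrow(pts),
                          intercept_um2 = NA_real_, residual_rms = NA_real_,
                          reason = "fewer than 2 populated lag bins in window"),
                     class = "mfx_diffusion_fit"))
  tau <- pts$lag_ms / 1000  # s
  y <- pts$msd_um2
  w <- pts$n_pairs
  if (intercept) {
    fit <- stats::lm.wfit(cbind(1, tau), y, w)
    b0 <- unname(fit$coefficients[1]); slope <- unname(fit$coefficients[2])
  } else {
    slope <- sum(w * tau * y) / sum(w * tau^2)
    b0 <- 0
  }
  resid <- y - (b0 + slope * tau)
  structure(list(d = slope / 6, window = window, n_lags = nrow(pts),
                 intercept_um2 = if (intercept) b0 else 0,
                 residual_rms = sqrt(sum(w * resid^2) / sum(w)),
                 reason = NULL),
            class = "mfx_diffusion_fit")
}

#' @export
print.mfx_diffusion_fit <- function(x, ...) {
  if (is.na(x$d))
    cat(sprintf("diffusion fit refused: %s\n", x$reason))
  else
    cat(sprintf("D = %.4g um^2/s (window %g-%g ms, %d lag bins)\n",
                x$d, x$window[1], x$window[2], x$n_lags))
  invisible(x)
}

#' Ensemble MSD and diffusion coefficients
#'
#' Pools the per-trajectory MSD curves of all accepted trajectories into
#' `ensemble_bins` linear lag bins up to `ensemble_tmax`; per bin, the
#' pooled value is the pair-count-weighted mean with a weighted s.e.m.
#' (effective sample size `(sum w)^2 / sum w^2`). The pooled curve is then
#' fitted over the microscopic and macroscopic windows.
#'
#' @param trajectories list of trajectories from [build_trajectories()].
#' @param params a [track_filter_params()].
#' @return list: `curve` (`lag_ms, msd_um2, sem, n_pairs`), `fit_micro`,
#'   `fit_macro`.
#' @export
ensemble_msd <- function(trajectories, params = track_filter_params()) {
  stopifnot(length(trajectories) >= 1)
  curves <- lapply(trajectories, compute_msd, params = params)
  all_bins <- do.call(rbind, curves[!vapply(curves, attr, logical(1), "empty")])
  stopifnot(nrow(all_bins) > 0)
  sp <- split(all_bins, all_bins$bin)
  curve <- do.call(rbind, lapply(sp, function(b) {
    w <- b$n_pairs
    mbar <- weighted.mean(b$msd_um2, w)
    n_eff <- sum(w)^2 / sum(w^2)
    wvar <- if (nrow(b) > 1) sum(w * (b$msd_um2 - mbar)^2) / sum(w) else 0
    data.frame(bin = b$bin[1], lag_ms = weighted.mean(b$lag_ms, w),
               msd_um2 = mbar,
               sem = if (n_eff > 1) sqrt(wvar / n_eff) else NA_real_,
               n_pairs = sum(w))
  }))
  curve <- curve[order(curve$bin), , drop = FALSE]
  rownames(curve) <- NULL
  attr(curve, "empty") <- FALSE
  class(curve) <- c("mfx_msd", "data.frame")
  list(curve = curve,
       fit_micro = fit_diffusion(curve, params$micro_window),
       fit_macro = fit_diffusion(curve, params$macro_window))
}

#' Per-trajectory diffusion coefficients
#'
#' Convenience wrapper: computes each trajectory's MSD and fits the
#' microscopic and macroscopic windows.
#'
#' @param trajectories list from [build_trajectories()].
#' @param params a [track_filter_params()].
#' @return data.frame `track_id, n_locs, d_micro, d_macro`.
#' @export
fit_trajectories <- function(trajectories, params = track_filter_params()) {
  rows <- lapply(trajectories, function(tr) {
    curve <- compute_msd(tr, params)
    data.frame(track_id = attr(tr, "track_id"), n_locs = nrow(tr),
               d_micro = fit_diffusion(curve, params$micro_window)$d,
               d_macro = fit_diffusion(curve, params$macro_window)$d)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(0), n_locs = integer(0),
               d_micro = numeric(0), d_macro = numeric(0))
  rownames(out) <- NULL
  out
}
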