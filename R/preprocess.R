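#' Preprocessing parameters for structural MINFLUX data
#'
#' Localization- and trace-level quality filters applied before clustering.
#' Defaults sit at the stringent end of the ranges used across datasets
#' (at least 10 localizations per trace, per-dimension s.d. below 10 nm,
#' EFO cutoff 130 kHz within the legal 120-150 kHz window).
#'
#' @param z_correction multiplicative z correction factor for refractive
#'   index mismatch (default 0.7).
#' @param min_locs_per_trace minimum localizations a trace must retain.
#' @param max_trace_sd a trace is dropped if any per-dimension raw s.d. is
#'   at or above this value (nm).
#' @param z_window `c(lo, hi)` in nm, or `"auto"` (mode of the per-trace
#'   mean-z histogram, plus/minus 100 nm) standing in for the manual
#'   membrane-plane threshold.
#' @param efo_max per-localization EFO cutoff (Hz); legal range
#'   120,000-150,000 in structural mode.
#' @return object of class `preprocess_params`.
#' @export
preprocess_params <- function(z_correction = 0.7, min_locs_per_trace = 10,
                              max_trace_sd = 10, z_window = "auto",
                              efo_max = 130000) {
  check_scalar(z_correction, "z_correction", lo = 1e-12, hi = 1)
  check_scalar(min_locs_per_trace, "min_locs_per_trace", lo = 1,
               integerish = TRUE)
  check_scalar(max_trace_sd, "max_trace_sd", lo = .Machine$double.eps)
  check_scalar(efo_max, "efo_max", lo = .Machine$double.eps)
  if (!identical(z_window, "auto")) {
    if (!(is.numeric(z_window) && length(z_window) == 2 &&
          z_window[1] < z_window[2]))
      stop_mfx("'z_window' must be \"auto\" or c(lo, hi) with lo < hi")
  }
  structure(list(z_correction = z_correction,
                 min_locs_per_trace = as.integer(min_locs_per_trace),
                 max_trace_sd = max_trace_sd, z_window = z_window,
                 efo_max = efo_max), class = "preprocess_params")
}

#' Apply the refractive-index z correction
#'
#' Multiplies z coordinates by `factor` (default 0.7), exactly once: the
#' returned table carries a flag and re-application is an error.
#'
#' @param table localization table.
#' @param factor correction factor in (0, 1].
#' @return corrected table with attribute `z_corrected = TRUE`.
#' @export
correct_z <- function(table, factor = 0.7) {
  check_scalar(factor, "factor", lo = 1e-12, hi = 1)
  if (isTRUE(attr(table, "z_corrected")))
    stop_mfx(paste("z correction already applied (attribute 'z_corrected');",
                   "refusing to apply it twice"))
  table$z <- table$z * factor
  attr(table, "z_corrected") <- TRUE
  table
}

#' Per-trace summary statistics
#'
#' @param table localization table.
#' @return data.frame with one row per trace: `trace_id, n_locs, sd_x, sd_y,
#'   sd_z, mean_x, mean_y, mean_z, mean_efo`. Single-localization traces get
#'   s.d. 0.
#' @export
trace_summary <- function(table) {
  if (!nrow(table))
    return(data.frame(trace_id = integer(0), n_locs = integer(0),
                      sd_x = numeric(0), sd_y = numeric(0), sd_z = numeric(0),
                      mean_x = numeric(0), mean_y = numeric(0),
                      mean_z = numeric(0), mean_efo = numeric(0)))
  sp <- split(seq_len(nrow(table)), table$trace_id)
  sd0 <- function(v) if (length(v) < 2) 0 else sd(v)
  out <- do.call(rbind, lapply(sp, function(idx) {
    data.frame(trace_id = table$trace_id[idx[1]], n_locs = length(idx),
               sd_x = sd0(table$x[idx]), sd_y = sd0(table$y[idx]),
               sd_z = sd0(table$z[idx]),
               mean_x = mean(table$x[idx]), mean_y = mean(table$y[idx]),
               mean_z = mean(table$z[idx]), mean_efo = mean(table$efo[idx]))
  }))
  rownames(out) <- NULL
  out
}

#' Trace-level quality filtering
#'
#' Filter order is fixed: (1) drop localizations with `efo > efo_max`;
#' (2) drop whole traces with fewer than `min_locs_per_trace` remaining
#' localizations; (3) drop traces with any per-dimension raw s.d. at or
#' above `max_trace_sd`; (4) keep traces whose mean z lies inside
#' `z_window` (`"auto"`: histogram mode of per-trace mean z, +/- 100 nm).
#'
#' @param table z-corrected localization table.
#' @param params a [preprocess_params()].
#' @return list with `table` (filtered localizations), `summaries`
#'   (trace summaries of the survivors), and `log` (rows/traces removed at
#'   each step, in order). An empty result is flagged
#'   (`log$no_traces_survive`), not an error.
#' @export
filter_traces <- function(table, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  log <- list(locs_in = nrow(table),
              traces_in = length(unique(table$trace_id)))

  keep <- table$efo <= params$efo_max
  log$locs_removed_efo <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  ts <- trace_summary(table)
  small <- ts$trace_id[ts$n_locs < params$min_locs_per_trace]
  log$traces_removed_min_locs <- length(small)
  ts <- ts[!ts$trace_id %in% small, , drop = FALSE]

  wide <- ts$trace_id[ts$sd_x >= params$max_trace_sd |
                      ts$sd_y >= params$max_trace_sd |
                      ts$sd_z >= params$max_trace_sd]
  log$traces_removed_sd <- length(wide)
  ts <- ts[!ts$trace_id %in% wide, , drop = FALSE]

  if (identical(params$z_window, "auto")) {
    zw <- if (nrow(ts)) {
      zc <- if (nrow(ts) > 1 && sd(ts$mean_z) > 0) {
        dz <- density(ts$mean_z)
        dz$x[which.max(dz$y)]
      } else ts$mean_z[1]
      c(zc - 100, zc + 100)
    } else c(-Inf, Inf)
  } else zw <- params$z_window
  outside <- ts$trace_id[ts$mean_z < zw[1] | ts$mean_z > zw[2]]
  log$traces_removed_z <- length(outside)
  log$z_window <- zw
  ts <- ts[!ts$trace_id %in% outside, , drop = FALSE]

  table <- table[table$trace_id %in% ts$trace_id, , drop = FALSE]
  rownames(table) <- NULL
  log$locs_out <- nrow(table)
  log$traces_out <- nrow(ts)
  if (!nrow(ts)) {
    log$no_traces_survive <- TRUE
    message("no traces survive filtering")
  }
  list(table = table, summaries = ts, log = log)
}

#' Estimate the EFO threshold between single- and two-emitter modes
#'
#' The EFO (effective photon frequency at offset) distribution of an
#' under-labelled sample has a single-dye mode and a second mode at about
#' twice that frequency (two active dyes). The cutoff is placed at the
#' antimode of a kernel-smoothed histogram between the first mode and twice
#' the first mode; in structural mode it is clamped to the legal
#' 120-150 kHz window.
#'
#' @param table localization table (needs at least 100 localizations).
#' @param mode `"structural"` (clamped) or `"tracking"` (unclamped).
#' @param clamp clamp interval (Hz) applied in structural mode.
#' @return cutoff in Hz, with attributes `mode1` (first EFO mode),
#'   `antimode` (unclamped estimate) and `unimodal`.
#' @export
estimate_efo_threshold <- function(table, mode = c("structural", "tracking"),
                                   clamp = c(120000, 150000)) {
  mode <- match.arg(mode)
  efo <- table$efo
  if (length(efo) < 100)
    stop_mfx("need at least 100 localizations to estimate the EFO threshold (got %d)",
             length(efo))
  if (sd(efo) == 0) {
    warning("degenerate (constant) EFO distribution; returning clamp midpoint",
            call. = FALSE)
    out <- mean(clamp)
    attributes(out) <- list(mode1 = efo[1], antimode = NA_real_,
                            unimodal = TRUE)
    return(out)
  }
  d <- density(efo, n = 2048)
  y <- d$y; x <- d$x
  imax <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(imax)) imax <- which.max(y)
  m1 <- x[imax[which.max(y[imax])]]   # dominant (single-emitter) mode
  lo <- which(x > m1 & x < 2 * m1)
  unimodal <- TRUE
  antimode <- NA_real_
  if (length(lo) > 2) {
    ianti <- lo[which.min(y[lo])]
    # genuine dip: density rises again past the antimode
    after <- which(x >= x[ianti])
    if (length(after) && max(y[after]) > y[ianti] * 1.1 &&
        y[ianti] < 0.9 * max(y)) {
      unimodal <- FALSE
      antimode <- x[ianti]
    }
  }
  if (unimodal) {
    warning("EFO histogram looks unimodal; returning clamp midpoint",
            call. = FALSE)
    cutoff <- mean(clamp)
  } else {
    cutoff <- antimode
  }
  if (mode == "structural") cutoff <- min(max(cutoff, clamp[1]), clamp[2])
  attributes(cutoff) <- list(mode1 = m1, antimode = antimode,
                             unimodal = unimodal)
  cutoff
}
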