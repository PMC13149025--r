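#' Trimer identification parameters
#'
#' A valid trimer is a DBSCAN cluster (over fluorophore positions) of
#' exactly three points, isolated from all other positions by more than
#' `isolation_eps`, in which every point has exactly `required_neighbours`
#' co-members at pairwise 3D distance strictly inside
#' (`nn_lo`, `nn_hi`) — a window spanning the range of interblade
#' separations expected from available cryo-EM structures.
#'
#' @param isolation_eps DBSCAN radius for isolation (nm, default 60).
#' @param isolation_minpts DBSCAN minimum points (default 3).
#' @param nn_lo,nn_hi open neighbour-distance window (nm, default 6-60).
#' @param required_neighbours neighbours each vertex must have within the
#'   window (default 2, i.e. both co-members).
#' @return object of class `trimer_params`.
#' @export
trimer_params <- function(isolation_eps = 60, isolation_minpts = 3,
                          nn_lo = 6, nn_hi = 60, required_neighbours = 2) {
  check_scalar(isolation_eps, "isolation_eps", lo = .Machine$double.eps)
  check_scalar(isolation_minpts, "isolation_minpts", lo = 1, integerish = TRUE)
  check_scalar(nn_lo, "nn_lo", lo = 0)
  check_scalar(nn_hi, "nn_hi", lo = nn_lo + .Machine$double.eps)
  check_scalar(required_neighbours, "required_neighbours", lo = 0,
               integerish = TRUE)
  if (isolation_eps < nn_hi)
    stop_mfx("need isolation_eps >= nn_hi")
  structure(list(isolation_eps = isolation_eps,
                 isolation_minpts = as.integer(isolation_minpts),
                 nn_lo = nn_lo, nn_hi = nn_hi,
                 required_neighbours = as.integer(required_neighbours)),
            class = "trimer_params")
}

#' Identify isolated trimers among fluorophore positions
#'
#' DBSCAN over positions with (`isolation_eps`, `isolation_minpts`) groups
#' positions; only clusters of exactly three survive (a fourth position
#' within the isolation radius merges in and disqualifies the cluster,
#' enforcing isolation). Within each size-3 cluster every point must have
#' exactly `required_neighbours` co-members at pairwise distance strictly
#' inside the window. Rejections are logged with a reason.
#'
#' @param positions data.frame of fluorophore positions
#'   (`x, y, z`, optionally `cluster_id`), after error filtering.
#' @param params a [trimer_params()].
#' @return list with `trimers` (data.frame: `molecule_id`, vertex
#'   coordinates `x1..z3`, `d12, d13, d23, d_mean`) and `rejections`
#'   (data.frame `group, size, reason`).
#' @export
identify_trimers <- function(positions, params = trimer_params()) {
  stopifnot(inherits(params, "trimer_params"))
  empty <- data.frame(molecule_id = integer(0),
                      x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), z2 = numeric(0),
                      x3 = numeric(0), y3 = numeric(0), z3 = numeric(0),
                      d12 = numeric(0), d13 = numeric(0), d23 = numeric(0),
                      d_mean = numeric(0))
  rejections <- data.frame(group = integer(0), size = integer(0),
                           reason = character(0))
  if (!nrow(positions))
    return(list(trimers = empty, rejections = rejections))
  pts <- as.matrix(positions[, c("x", "y", "z")])
  lab <- dbscan3d(pts, params$isolation_eps, params$isolation_minpts)
  out <- list(); mol <- 0L
  for (g in setdiff(unique(lab), 0L)) {
    idx <- which(lab == g)
    if (length(idx) != 3L) {
      rejections <- rbind(rejections, data.frame(
        group = g, size = length(idx), reason = "size_not_3"))
      next
    }
    v <- pts[idx, , drop = FALSE]
    d <- c(d12 = sqrt(sum((v[1, ] - v[2, ])^2)),
           d13 = sqrt(sum((v[1, ] - v[3, ])^2)),
           d23 = sqrt(sum((v[2, ] - v[3, ])^2)))
    # per-point neighbour counts inside the open window
    pair_ok <- d > params$nn_lo & d < params$nn_hi
    nb <- c(sum(pair_ok[c("d12", "d13")]),
            sum(pair_ok[c("d12", "d23")]),
            sum(pair_ok[c("d13", "d23")]))
    if (!all(nb == params$required_neighbours)) {
      reason <- if (any(d <= params$nn_lo)) "pair_too_close"
                else "pair_out_of_window"
      rejections <- rbind(rejections, data.frame(
        group = g, size = 3L, reason = reason))
      next
    }
    mol <- mol + 1L
    out[[mol]] <- data.frame(
      molecule_id = mol,
      x1 = v[1, 1], y1 = v[1, 2], z1 = v[1, 3],
      x2 = v[2, 1], y2 = v[2, 2], z2 = v[2, 3],
      x3 = v[3, 1], y3 = v[3, 2], z3 = v[3, 3],
      d12 = unname(d["d12"]), d13 = unname(d["d13"]),
      d23 = unname(d["d23"]), d_mean = mean(d))
  }
  # DBSCAN noise points are singletons/pairs: count them as rejected pairs
  # only when they formed no cluster at all (informational, not per-group).
  trimers <- if (length(out)) do.call(rbind, out) else empty
  rownames(trimers) <- NULL
  list(trimers = trimers, rejections = rejections)
}

#' Interblade distance distribution and summary
#'
#' Per-molecule interblade distance is the mean of the three pairwise 3D
#' distances (`d_mean`). The summary reports median with a seeded 95%
#' percentile-bootstrap CI, mean, s.d., variance and n.
#'
#' @param trimers the `trimers` data.frame from [identify_trimers()].
#' @param n_boot bootstrap resamples for the median CI.
#' @param seed RNG seed for the bootstrap.
#' @return list with `distances` (columns `molecule_id, d12, d13, d23,
#'   d_mean`) and `summary` (named list; `empty = TRUE` when no trimer).
#' @export
interblade_distances <- function(trimers, n_boot = 10000, seed = 1L) {
  distances <- trimers[, c("molecule_id", "d12", "d13", "d23", "d_mean"),
                       drop = FALSE]
  if (!nrow(distances))
    return(list(distances = distances,
                summary = list(empty = TRUE, n = 0L)))
  d <- distances$d_mean
  ci <- if (length(d) >= 3) bootstrap_median_ci(d, n_boot = n_boot, seed = seed)
        else list(ci_lo = NA_real_, ci_hi = NA_real_)
  list(distances = distances,
       summary = list(empty = FALSE, n = length(d), median = median(d),
                      ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
                      mean = mean(d), sd = sd(d), var = var(d)))
}
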