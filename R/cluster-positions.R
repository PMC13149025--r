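#' Clustering parameters for fluorophore position assignment
#'
#' Two-step DBSCAN (noise removal, then re-clustering) followed by a
#' spherical Gaussian-mixture EM refinement. Defaults follow the stringent
#' parameter set used for DNA-PAINT MINFLUX data: eps 10 nm / 5 points,
#' then eps 7 nm / 5 points, GMM initial sigma 5 nm (about the localization
#' error), 10 nm position error cutoff.
#'
#' @param eps1,minpts1 first DBSCAN pass (noise identification/removal).
#' @param eps2,minpts2 second DBSCAN pass (cluster assignment). `eps1 >=
#'   eps2` is required.
#' @param gmm_init_sigma initial spherical s.d. (nm) of each EM component.
#' @param max_position_error positions whose member-localization s.d.
#'   exceeds this (nm) are dropped.
#' @param em_tol relative log-likelihood change declaring convergence.
#' @param em_max_iter maximum EM iterations.
#' @return object of class `cluster_params`.
#' @export
cluster_params <- function(eps1 = 10, minpts1 = 5, eps2 = 7, minpts2 = 5,
                           gmm_init_sigma = 5, max_position_error = 10,
                           em_tol = 1e-6, em_max_iter = 500) {
  check_scalar(eps1, "eps1", lo = .Machine$double.eps)
  check_scalar(eps2, "eps2", lo = .Machine$double.eps)
  if (eps1 < eps2) stop_mfx("need eps1 >= eps2 (noise pass is the looser one)")
  check_scalar(minpts1, "minpts1", lo = 1, integerish = TRUE)
  check_scalar(minpts2, "minpts2", lo = 1, integerish = TRUE)
  check_scalar(gmm_init_sigma, "gmm_init_sigma", lo = .Machine$double.eps)
  check_scalar(max_position_error, "max_position_error", lo = 0)
  check_scalar(em_tol, "em_tol", lo = 0)
  check_scalar(em_max_iter, "em_max_iter", lo = 1, integerish = TRUE)
  structure(list(eps1 = eps1, minpts1 = as.integer(minpts1), eps2 = eps2,
                 minpts2 = as.integer(minpts2),
                 gmm_init_sigma = gmm_init_sigma,
                 max_position_error = max_position_error, em_tol = em_tol,
                 em_max_iter = as.integer(em_max_iter)),
            class = "cluster_params")
}

#' DBSCAN over 3D points
#'
#' Deterministic density-based clustering; the epsilon-neighbourhood count
#' includes the query point itself, and ties are resolved by input order
#' (classic FIFO expansion).
#'
#' @param pts numeric matrix (n x 3), coordinates in nm.
#' @param eps neighbourhood radius (nm).
#' @param minpts minimum neighbourhood size (including the point) for a
#'   core point.
#' @return integer vector of cluster labels; 0 marks noise.
#' @export
dbscan3d <- function(pts, eps, minpts) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3, is.numeric(pts))
  check_scalar(eps, "eps", lo = .Machine$double.eps)
  check_scalar(minpts, "minpts", lo = 1, integerish = TRUE)
  .dbscan3d_cpp(pts, eps, as.integer(minpts))
}

#' Two-step DBSCAN labelling of localizations
#'
#' Step 1 (`eps1`, `minpts1`) identifies and discards noise; step 2
#' (`eps2`, `minpts2`) re-clusters the surviving localizations. Clustering
#' is performed on localizations (not trace means) in 3D. Input rows are
#' first stably sorted on (`trace_id`, `t`) so labelling is deterministic.
#'
#' @param table preprocessed localization table.
#' @param params a [cluster_params()].
#' @return the de-noised table with an integer `cluster` column (step-2
#'   cluster id; 0 for the rare step-2 noise points).
#' @export
cluster_localizations <- function(table, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  if (!nrow(table)) {
    table$cluster <- integer(0)
    return(table)
  }
  table <- table[order(table$trace_id, table$t), , drop = FALSE]
  pts <- as.matrix(table[, c("x", "y", "z")])
  lab1 <- dbscan3d(pts, params$eps1, params$minpts1)
  keep <- lab1 != 0L
  table <- table[keep, , drop = FALSE]
  lab2 <- if (any(keep)) dbscan3d(pts[keep, , drop = FALSE],
                                  params$eps2, params$minpts2) else integer(0)
  table$cluster <- lab2
  rownames(table) <- NULL
  table
}

#' Fit fluorophore positions by spherical Gaussian-mixture EM
#'
#' One spherical Gaussian component per step-2 DBSCAN cluster; means are
#' initialized at cluster centroids and the s.d. at `gmm_init_sigma`. EM is
#' run jointly over each spatially connected neighbourhood (clusters whose
#' centroids link within `2 * eps1`, single linkage) so that nearby
#' clusters compete for localizations, and to convergence at `em_tol`.
#' The position is the component mean; its error is the s.d. of the member
#' localizations (root mean per-dimension variance); positions with error
#' above `max_position_error` are dropped and logged.
#'
#' @param labelled output of [cluster_localizations()] (needs a `cluster`
#'   column).
#' @param params a [cluster_params()].
#' @param debug if `TRUE`, assert log-likelihood monotonicity each EM
#'   iteration.
#' @return list with `positions` (data.frame `cluster_id, x, y, z, error,
#'   n_locs, converged`) and `log` (drop counts by reason).
#' @export
fit_positions <- function(labelled, params = cluster_params(), debug = FALSE) {
  stopifnot(inherits(params, "cluster_params"), "cluster" %in% names(labelled))
  labelled <- labelled[labelled$cluster != 0L, , drop = FALSE]
  empty <- data.frame(cluster_id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), error = numeric(0), n_locs = integer(0),
                      converged = logical(0))
  if (!nrow(labelled))
    return(list(positions = empty,
                log = list(dropped_error = 0L, dropped_small = 0L,
                           nonconverged = 0L)))

  pts <- as.matrix(labelled[, c("x", "y", "z")])
  cl_ids <- sort(unique(labelled$cluster))
  centroids <- t(vapply(cl_ids, function(id)
    colMeans(pts[labelled$cluster == id, , drop = FALSE]), numeric(3)))

  comp <- if (length(cl_ids) > 1) {
    hc <- hclust(dist(centroids), method = "single")
    cutree(hc, h = 2 * params$eps1)
  } else 1L

  out <- list(); log <- list(dropped_error = 0L, dropped_small = 0L,
                             nonconverged = 0L)
  for (cc in unique(comp)) {
    ids <- cl_ids[comp == cc]
    sel <- labelled$cluster %in% ids
    x <- pts[sel, , drop = FALSE]
    init_mu <- centroids[comp == cc, , drop = FALSE]
    fit <- em_gmm_spherical(x, init_mu, params$gmm_init_sigma,
                            tol = params$em_tol,
                            max_iter = params$em_max_iter, debug = debug)
    if (!fit$converged) log$nonconverged <- log$nonconverged + length(ids)
    assign <- max.col(fit$resp)
    for (k in seq_along(ids)) {
      members <- x[assign == k, , drop = FALSE]
      n_k <- nrow(members)
      if (n_k < params$minpts2) { log$dropped_small <- log$dropped_small + 1L; next }
      err <- sqrt(mean(apply(members, 2, var)))
      if (!is.finite(err)) err <- 0
      if (err > params$max_position_error) {
        log$dropped_error <- log$dropped_error + 1L
        next
      }
      mu <- if (fit$converged) fit$mu[k, ] else init_mu[k, ]
      out[[length(out) + 1L]] <- data.frame(
        cluster_id = ids[k], x = mu[1], y = mu[2], z = mu[3],
        error = err, n_locs = n_k, converged = fit$converged)
    }
  }
  positions <- if (length(out)) do.call(rbind, out) else empty
  positions <- positions[order(positions$cluster_id), , drop = FALSE]
  rownames(positions) <- NULL
  list(positions = positions, log = log)
}

# Spherical-covariance Gaussian mixture EM with fixed component count.
# Variance floored at 1 nm^2 to prevent collapse onto a single point.
em_gmm_spherical <- function(x, mu, init_sigma, tol = 1e-6, max_iter = 500,
                             debug = FALSE, var_floor = 1) {
  n <- nrow(x); K <- nrow(mu)
  sig2 <- rep(max(init_sigma^2, var_floor), K)
  w <- rep(1 / K, K)
  ll_old <- -Inf
  converged <- FALSE
  resp <- matrix(1, n, 1)
  for (iter in seq_len(max_iter)) {
    # E step: log responsibilities, spherical 3D Gaussian
    logd <- vapply(seq_len(K), function(k) {
      d2 <- rowSums(sweep(x, 2, mu[k, ])^2)
      log(w[k]) - 1.5 * log(2 * pi * sig2[k]) - d2 / (2 * sig2[k])
    }, numeric(n))
    logd <- matrix(logd, nrow = n)
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    if (debug && ll < ll_old - 1e-6 * abs(ll_old))
      stop_mfx("EM log-likelihood decreased (%.6g -> %.6g)", ll_old, ll)
    resp <- exp(logd - lse)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * abs(ll_old)) { converged <- TRUE; break }
    ll_old <- ll
    # M step
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-12)
    w <- nk / n
    mu <- t(vapply(seq_len(K), function(k)
      colSums(x * resp[, k]) / nk[k], numeric(3)))
    sig2 <- vapply(seq_len(K), function(k) {
      d2 <- rowSums(sweep(x, 2, mu[k, ])^2)
      max(sum(resp[, k] * d2) / (3 * nk[k]), var_floor)
    }, numeric(1))
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations", max_iter),
            call. = FALSE)
  list(mu = mu, sigma2 = sig2, weight = w, resp = resp,
       loglik = ll_old, converged = converged)
}
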