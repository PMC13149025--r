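# Independent oracles and fixture builders shared across test files.

# Textbook DBSCAN: all-pairs distance matrix, FIFO seed expansion, input
# order processing; neighbourhood counts include the query point (same
# stated convention as the pipeline, independently implemented).
dbscan_oracle <- function(pts, eps, minpts) {
  n <- nrow(pts)
  labels <- integer(n)
  if (!n) return(labels)
  dm <- as.matrix(dist(pts))
  nbrs <- lapply(seq_len(n), function(i) which(dm[i, ] <= eps))
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    if (length(nbrs[[i]]) < minpts) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbrs[[i]]
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (labels[q] == 0L) labels[q] <- cl
      if (visited[q]) next
      visited[q] <- TRUE
      labels[q] <- cl
      if (length(nbrs[[q]]) >= minpts) queue <- c(queue, nbrs[[q]])
    }
  }
  labels
}

# Canonical relabelling by order of first appearance, so two DBSCAN runs can
# be compared as partitions (noise label 0 kept as-is).
canonical_labels <- function(lab) {
  ids <- unique(lab[lab != 0L])
  match(lab, ids, nomatch = 0L) * (lab != 0L)
}

# Equilateral triangle vertices (rows) with side `side`, centred at (cx, cy),
# in-plane rotation theta, at height z.
triangle_vertices <- function(side, cx = 0, cy = 0, theta = 0, z = 0) {
  ang <- theta + c(0, 2, 4) * pi / 3
  R <- side / sqrt(3)
  cbind(x = cx + R * cos(ang), y = cy + R * sin(ang), z = rep(z, 3))
}

# Canonical localization table from coordinate vectors with benign
# defaults for the remaining columns.
loc_table <- function(x, y, z, trace_id = 1L, t = seq_along(x) * 1e-3,
                      efo = 75000, valid = TRUE) {
  data.frame(trace_id = trace_id, t = t, x = x, y = y, z = z,
             efo = efo, valid = valid)
}

# 3D rigid rotation matrix from an axis (unit vector) and angle.
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  ct <- cos(angle); st <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * outer(a, a)
}

# Match measured trimer centroids to ground-truth trimer centres; returns
# the number of truth trimers with a measured counterpart within `tol` nm.
count_recovered_trimers <- function(trimers, truth, tol = 10) {
  if (!nrow(trimers)) return(0L)
  meas <- cbind((trimers$x1 + trimers$x2 + trimers$x3) / 3,
                (trimers$y1 + trimers$y2 + trimers$y3) / 3)
  truth_xy <- cbind(truth$cx, truth$cy)
  hit <- logical(nrow(truth_xy))
  for (i in seq_len(nrow(meas))) {
    d2 <- (truth_xy[, 1] - meas[i, 1])^2 + (truth_xy[, 2] - meas[i, 2])^2
    j <- which.min(d2)
    if (d2[j] <= tol^2) hit[j] <- TRUE
  }
  sum(hit)
}
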