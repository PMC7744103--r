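# Independent oracles and small fixture builders used across tests.

# Exhaustive k-means oracle: minimal WCSS over every assignment of the rows
# of `m` to at most k clusters (feasible for n <= 10, k <= 3).
oracle_min_wcss <- function(m, k) {
  n <- nrow(m)
  grids <- rep(list(seq_len(k)), n)
  assignments <- as.matrix(expand.grid(grids))
  best <- Inf
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    w <- 0
    for (cl in unique(a)) {
      rows <- m[a == cl, , drop = FALSE]
      cen <- colMeans(rows)
      w <- w + sum(sweep(rows, 2, cen)^2)
    }
    if (w < best) best <- w
  }
  best
}

# Brute-force 3D convex hull metrics: enumerate all triangles whose plane
# has every other point on one side; sum facet areas, and volume via signed
# tetrahedra against the centroid.
oracle_hull_metrics <- function(p) {
  n <- nrow(p)
  ctr <- colMeans(p)
  area <- 0
  vol <- 0
  combs <- utils::combn(n, 3)
  for (c_i in seq_len(ncol(combs))) {
    tri <- combs[, c_i]
    a <- p[tri[1], ]; b <- p[tri[2], ]; cc <- p[tri[3], ]
    nrm <- c(
      (b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
      (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
      (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
    )
    if (sum(nrm^2) == 0) next
    s <- (p - matrix(a, n, 3, byrow = TRUE)) %*% nrm
    s <- s[-tri]
    if (all(s <= 1e-9 * max(abs(p))) || all(s >= -1e-9 * max(abs(p)))) {
      area <- area + sqrt(sum(nrm^2)) / 2
      vol <- vol + abs(sum((a - ctr) *
        c((b[2] - ctr[2]) * (cc[3] - ctr[3]) - (b[3] - ctr[3]) * (cc[2] - ctr[2]),
          (b[3] - ctr[3]) * (cc[1] - ctr[1]) - (b[1] - ctr[1]) * (cc[3] - ctr[3]),
          (b[1] - ctr[1]) * (cc[2] - ctr[2]) - (b[2] - ctr[2]) * (cc[1] - ctr[1])))) / 6
    }
  }
  c(volume = vol, area = area)
}

# Dense-resampling Sholl oracle: subdivide every segment into `pieces`
# colinear sub-segments and apply the same endpoint-straddling rule.
oracle_sholl <- function(recon, step = 10, center = c(0, 0, 0),
                         pieces = 200) {
  idx <- setNames(seq_len(nrow(recon)), recon$id)
  segs <- recon[recon$parent != -1L, ]
  dmax <- max(sqrt((recon$x - center[1])^2 + (recon$y - center[2])^2 +
                     (recon$z - center[3])^2))
  radii <- seq(step, dmax + step, by = step)
  counts <- integer(length(radii))
  for (i in seq_len(nrow(segs))) {
    p1 <- unlist(recon[idx[as.character(segs$parent[i])], c("x", "y", "z")])
    p2 <- unlist(segs[i, c("x", "y", "z")])
    tgrid <- seq(0, 1, length.out = pieces + 1)
    pts <- outer(1 - tgrid, p1) + outer(tgrid, p2)
    d <- sqrt(rowSums(sweep(pts, 2, center)^2))
    for (j in seq_along(radii)) {
      r <- radii[j]
      lo <- pmin(d[-length(d)], d[-1])
      hi <- pmax(d[-length(d)], d[-1])
      counts[j] <- counts[j] + sum(lo < r & hi > r)
    }
  }
  tibble::tibble(radius_um = radii, crossings = counts)
}

# Minimal hand-built SWC trees.
straight_neurite <- function(length_um = 100, n = 8) {
  tibble::tibble(
    id = seq_len(n), type = c(1L, rep(3L, n - 1)),
    x = seq(0, length_um, length.out = n), y = 0, z = 0,
    radius = 1, parent = c(-1L, seq_len(n - 1))
  )
}

y_tree <- function(branch_at = 25, arm = 75) {
  tibble::tibble(
    id = 1:5, type = c(1L, 3L, 3L, 3L, 3L),
    x = c(0, branch_at, branch_at + arm, branch_at + arm * cos(0.6),
          branch_at + arm * cos(-0.6)),
    y = c(0, 0, 0, arm * sin(0.6), arm * sin(-0.6)),
    z = 0, radius = 1, parent = c(-1L, 1L, 2L, 2L, 2L)
  )
}

# Default full current-step protocol used in recovery tests.
recovery_protocol <- function(sampling_khz = 40) {
  step_protocol(
    step_amplitudes = c(-300, 100, 200, 500),
    onset_ms = 100, offset_ms = 1100, duration_ms = 1300,
    sampling_khz = sampling_khz
  )
}
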