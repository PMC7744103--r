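# Incremental 3D convex hull (triangular facets), written for the modest
# point counts of single-neuron reconstructions. Returns facet indices
# oriented outward; degenerate (rank < 3) inputs are reported as such so
# callers can fall back to planar measures.

hull3d <- function(p) {
  p <- unique(round(p, 12))
  n <- nrow(p)
  scale <- max(1, max(abs(p)))
  eps <- 1e-9 * scale
  if (n < 4) return(list(degenerate = TRUE, points = p))

  # Initial extreme tetrahedron.
  i1 <- which.min(p[, 1])
  d1 <- sqrt(rowSums((p - matrix(p[i1, ], n, 3, byrow = TRUE))^2))
  i2 <- which.max(d1)
  if (d1[i2] < eps) return(list(degenerate = TRUE, points = p))
  ab <- p[i2, ] - p[i1, ]
  ap <- p - matrix(p[i1, ], n, 3, byrow = TRUE)
  cr <- cbind(
    ap[, 2] * ab[3] - ap[, 3] * ab[2],
    ap[, 3] * ab[1] - ap[, 1] * ab[3],
    ap[, 1] * ab[2] - ap[, 2] * ab[1]
  )
  dline <- sqrt(rowSums(cr^2)) / sqrt(sum(ab^2))
  i3 <- which.max(dline)
  if (dline[i3] < eps) return(list(degenerate = TRUE, points = p, rank = 1))
  nrm <- cross3(p[i2, ] - p[i1, ], p[i3, ] - p[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  dplane <- abs(ap %*% nrm)
  i4 <- which.max(dplane)
  if (dplane[i4] < eps) {
    return(list(degenerate = TRUE, points = p, rank = 2, normal = nrm))
  }

  interior <- colMeans(p[c(i1, i2, i3, i4), ])
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- t(apply(faces, 1, orient_face, p = p, interior = interior))

  for (q in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    sd_q <- face_signed_dist(p, faces, p[q, ])
    vis <- which(sd_q > eps)
    if (length(vis) == 0) next
    vis_faces <- faces[vis, , drop = FALSE]
    edges <- rbind(
      vis_faces[, c(1, 2), drop = FALSE],
      vis_faces[, c(2, 3), drop = FALSE],
      vis_faces[, c(3, 1), drop = FALSE]
    )
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    faces <- faces[-vis, , drop = FALSE]
    new_faces <- cbind(horizon, q)
    new_faces <- t(apply(new_faces, 1, orient_face, p = p,
                         interior = interior))
    faces <- rbind(faces, new_faces)
  }
  list(degenerate = FALSE, points = p, faces = faces, interior = interior)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

orient_face <- function(f, p, interior) {
  nrm <- cross3(p[f[2], ] - p[f[1], ], p[f[3], ] - p[f[1], ])
  if (sum(nrm * (interior - p[f[1], ])) > 0) f[c(1, 3, 2)] else f
}

# Signed distances of point q from each face plane (positive = outside).
face_signed_dist <- function(p, faces, q) {
  vapply(seq_len(nrow(faces)), function(i) {
    f <- faces[i, ]
    nrm <- cross3(p[f[2], ] - p[f[1], ], p[f[3], ] - p[f[1], ])
    nl <- sqrt(sum(nrm^2))
    if (nl == 0) return(-Inf)
    sum(nrm / nl * (q - p[f[1], ]))
  }, numeric(1))
}

hull3d_metrics <- function(h) {
  p <- h$points
  vol <- 0
  area <- 0
  for (i in seq_len(nrow(h$faces))) {
    f <- h$faces[i, ]
    a <- p[f[1], ] - h$interior
    b <- p[f[2], ] - h$interior
    cc <- p[f[3], ] - h$interior
    vol <- vol + abs(sum(a * cross3(b, cc))) / 6
    area <- area + sqrt(sum(cross3(p[f[2], ] - p[f[1], ],
                                         p[f[3], ] - p[f[1], ])^2)) / 2
  }
  c(volume = vol, surface_area = area)
}
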