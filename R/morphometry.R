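# Reconstruction morphometry: SWC I/O, caliper axis extents, convex-hull
# volume/surface area, Sholl profiles, and the two-sample K-S comparison of
# Sholl profiles.

#' Read / write SWC reconstructions
#'
#' SWC: whitespace-separated columns `id type x y z radius parent` (um,
#' 1-based ids, parent -1 for the single root), `#` comments. Validation
#' errors name the offending line; parents must precede their children.
#'
#' @param path File path.
#' @return `read_swc()`: a reconstruction tibble with attribute `soma` (root
#'   coordinates). `write_swc()`: the path, invisibly.
#' @export
read_swc <- function(path) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0) abort("empty SWC file")
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 7L)
  if (length(bad) > 0) {
    abort(sprintf("line %d: expected 7 fields, found %d",
                  lineno[bad[1]], lengths(fields)[bad[1]]))
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  )
  bad <- which(apply(m, 1, anyNA))
  if (length(bad) > 0) {
    abort(sprintf("line %d: non-numeric field", lineno[bad[1]]))
  }
  out <- tibble(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  )
  validate_recon(out, lineno)
  root <- out[out$parent == -1L, ]
  attr(out, "soma") <- c(x = root$x[1], y = root$y[1], z = root$z[1])
  out
}

validate_recon <- function(recon, lineno = seq_len(nrow(recon))) {
  if (anyDuplicated(recon$id)) {
    i <- which(duplicated(recon$id))[1]
    abort(sprintf("line %d: duplicate node id %d", lineno[i], recon$id[i]))
  }
  roots <- which(recon$parent == -1L)
  if (length(roots) != 1L) {
    abort(sprintf("expected exactly one root (parent -1), found %d",
                  length(roots)))
  }
  seen <- integer()
  for (i in seq_len(nrow(recon))) {
    p <- recon$parent[i]
    if (p != -1L && !(p %in% seen)) {
      abort(sprintf(
        "line %d: parent %d of node %d does not precede it",
        lineno[i], p, recon$id[i]
      ))
    }
    seen <- c(seen, recon$id[i])
  }
  if (!all(is.finite(unlist(recon[, c("x", "y", "z", "radius")])))) {
    abort("non-finite coordinates")
  }
  invisible(recon)
}

#' @rdname read_swc
#' @param recon Reconstruction tibble (`id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`).
#' @export
write_swc <- function(recon, path) {
  validate_recon(recon)
  lines <- sprintf(
    "%d %d %.6f %.6f %.6f %.6f %d",
    recon$id, recon$type, recon$x, recon$y, recon$z, recon$radius,
    recon$parent
  )
  writeLines(c("# SWC reconstruction", lines), path)
  invisible(path)
}

# Maximum pairwise distance (Feret diameter) of a point matrix.
feret_diameter <- function(p) {
  max(dist(p))
}

# Indices of a pair realizing the Feret diameter.
feret_pair <- function(p) {
  d <- as.matrix(dist(p))
  idx <- which(d == max(d), arr.ind = TRUE)[1, ]
  as.integer(idx)
}

# Minimal caliper width of a planar point set (rotating calipers over hull
# edges: the width is the smallest over edges of the maximal point distance
# from the edge's line).
min_caliper_width <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 2) return(0)
  h <- grDevices::chull(xy)
  hp <- xy[h, , drop = FALSE]
  k <- nrow(hp)
  if (k == 2) return(0)
  widths <- vapply(seq_len(k), function(i) {
    a <- hp[i, ]
    b <- hp[if (i == k) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    max(abs((hp[, 1] - a[1]) * nrm[1] + (hp[, 2] - a[2]) * nrm[2]))
  }, numeric(1))
  min(widths)
}

#' Longest and shortest axis of a reconstruction
#'
#' The longest axis is the Feret diameter of the node set; the shortest is
#' the minimal caliper width. In `"projection"` mode (default; slice
#' reconstructions are nearly planar) both are measured in the x-y plane
#' with rotating calipers; in `"3D"` mode the longest axis uses full 3D
#' distances and the shortest is the minimal width over directions
#' orthogonal to the longest axis.
#'
#' @param recon Reconstruction tibble.
#' @param mode `"projection"` or `"3D"`.
#' @return Tibble with `longest_um` and `shortest_um`.
#' @export
axis_extents <- function(recon, mode = c("projection", "3D")) {
  mode <- match.arg(mode)
  if (nrow(recon) < 2) abort("need at least 2 nodes")
  if (mode == "projection") {
    xy <- cbind(recon$x, recon$y)
    return(tibble(longest_um = feret_diameter(xy),
                  shortest_um = min_caliper_width(xy)))
  }
  p <- cbind(recon$x, recon$y, recon$z)
  pair <- feret_pair(p)
  longest <- sqrt(sum((p[pair[1], ] - p[pair[2], ])^2))
  u <- (p[pair[2], ] - p[pair[1], ]) / longest
  # Orthonormal basis of the plane orthogonal to the longest axis.
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- cross3(u, ref)
  v <- v / sqrt(sum(v^2))
  w <- cross3(u, v)
  width_at <- function(phi) {
    dir <- cos(phi) * v + sin(phi) * w
    proj <- p %*% dir
    max(proj) - min(proj)
  }
  grid <- seq(0, pi, length.out = 361)[-361]
  wds <- vapply(grid, width_at, numeric(1))
  i <- which.min(wds)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  shortest <- optimise(width_at, c(lo, hi))$objective
  tibble(longest_um = longest, shortest_um = min(shortest, min(wds)))
}

#' Convex-hull volume and surface area of a reconstruction
#'
#' 3D convex hull of all node coordinates; volume as the sum of
#' tetrahedra against an interior point, surface area as the facet-area
#' sum. Coplanar node sets get volume 0 (flagged) with the area of the
#' planar hull polygon.
#'
#' @param recon Reconstruction tibble.
#' @return Tibble with `volume_um3`, `surface_area_um2`, `degenerate`.
#' @export
convex_hull_metrics <- function(recon) {
  p <- cbind(recon$x, recon$y, recon$z)
  h <- hull3d(p)
  if (isTRUE(h$degenerate)) {
    pts <- h$points
    area <- 0
    if (!is.null(h$normal) && nrow(pts) >= 3) {
      # Planar set: polygon area of the 2D hull in the plane basis.
      nrm <- h$normal
      ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- cross3(nrm, ref)
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- cross3(nrm, e1)
      uv <- cbind(pts %*% e1, pts %*% e2)
      hidx <- grDevices::chull(uv)
      hp <- uv[hidx, , drop = FALSE]
      k <- nrow(hp)
      if (k >= 3) {
        j <- c(2:k, 1)
        area <- abs(sum(hp[, 1] * hp[j, 2] - hp[j, 1] * hp[, 2])) / 2
      }
    }
    return(tibble(volume_um3 = 0, surface_area_um2 = area, degenerate = TRUE))
  }
  m <- hull3d_metrics(h)
  tibble(volume_um3 = m[["volume"]], surface_area_um2 = m[["surface_area"]],
         degenerate = FALSE)
}

#' Sholl profile of a reconstruction
#'
#' For each shell radius `r` (multiples of `step` out to the maximal node
#' distance), counts neurite segments crossing the sphere of radius `r`
#' centred on the soma: a parent-child segment with endpoint distances
#' `d1 < r < d2` contributes one crossing; tangency is ignored.
#'
#' @param recon Reconstruction tibble.
#' @param step Shell spacing (um).
#' @param center Sphere centre (length-3 numeric); defaults to the `soma`
#'   attribute or the root node.
#' @return Tibble (`radius_um`, `crossings`) of class `stellate_sholl`.
#' @export
sholl <- function(recon, step = 10, center = NULL) {
  if (step <= 0) abort("`step` must be positive")
  center <- center %||% attr(recon, "soma") %||%
    unlist(recon[recon$parent == -1L, c("x", "y", "z")][1, ])
  p <- cbind(recon$x - center[1], recon$y - center[2], recon$z - center[3])
  d <- sqrt(rowSums(p^2))
  names(d) <- recon$id
  seg <- recon[recon$parent != -1L, ]
  d1 <- d[as.character(seg$parent)]
  d2 <- d[as.character(seg$id)]
  lo <- pmin(d1, d2)
  hi <- pmax(d1, d2)
  radii <- seq(step, max(d) + step, by = step)
  crossings <- vapply(radii, function(r) sum(lo < r & hi > r), integer(1))
  structure(
    tibble(radius_um = radii, crossings = crossings),
    class = c("stellate_sholl", class(tibble())),
    center = center, step = step
  )
}

#' Two-sample Kolmogorov-Smirnov comparison of Sholl profiles
#'
#' Treats each profile as a sample of crossing radii weighted by
#' intersection counts and compares the two radius distributions with the
#' two-sample K-S test (asymptotic p), the comparison used to show the
#' small cells' branching concentrates nearer the soma.
#'
#' @param profile_a,profile_b Sholl profiles (tibbles with `radius_um`,
#'   `crossings`), or raw numeric samples of radii.
#' @return Tibble (`statistic`, `p_value`, `n_a`, `n_b`).
#' @export
ks_two_sample <- function(profile_a, profile_b) {
  expand <- function(pr) {
    if (is.data.frame(pr)) rep(pr$radius_um, pr$crossings) else as.numeric(pr)
  }
  a <- expand(profile_a)
  b <- expand(profile_b)
  if (length(a) == 0 || length(b) == 0) abort("empty profile")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n_a = length(a), n_b = length(b))
}
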