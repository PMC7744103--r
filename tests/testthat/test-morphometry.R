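# SWC I/O, caliper extents, convex hulls, Sholl profiles, K-S comparison.

test_that("SWC files round-trip and validation names the offending line", {
  rec <- y_tree()
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(rec, path)
  back <- read_swc(path)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-6,
               ignore_attr = TRUE)

  gen <- generate_morphology(morph_spec(), seed = 1)
  p2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(gen, p2)
  expect_equal(read_swc(p2)$x, gen$x, tolerance = 1e-5)

  bad <- rec
  bad$parent[2] <- 4L  # child precedes its parent
  pb <- withr::local_tempfile(fileext = ".swc")
  writeLines(sprintf("%d %d %f %f %f %f %d", bad$id, bad$type, bad$x,
                     bad$y, bad$z, bad$radius, bad$parent), pb)
  expect_error(read_swc(pb), "line 2")

  writeLines(c("1 1 0 0 0 1 -1", "2 3 a 0 0 1 1"), pb)
  expect_error(read_swc(pb), "non-numeric")
  writeLines(c("1 1 0 0 0 1 -1", "2 3 0 0 1 1"), pb)
  expect_error(read_swc(pb), "7 fields")
  writeLines(c("1 1 0 0 0 1 -1", "2 3 0 0 0 1 -1"), pb)
  expect_error(read_swc(pb), "one root")
})

test_that("axis extents match hand geometry", {
  two <- tibble::tibble(id = 1:2, type = 3L, x = c(0, 100), y = 0, z = 0,
                        radius = 1, parent = c(-1L, 1L))
  ax <- axis_extents(two)
  expect_equal(ax$longest_um, 100)
  expect_equal(ax$shortest_um, 0)

  # 50 x 20 rectangle of nodes: diagonal sqrt(2900), caliper width 20.
  g <- expand.grid(x = seq(0, 50, by = 5), y = seq(0, 20, by = 5))
  rect <- tibble::tibble(id = seq_len(nrow(g)), type = 3L, x = g$x, y = g$y,
                         z = 0, radius = 1,
                         parent = c(-1L, seq_len(nrow(g) - 1)))
  ax2 <- axis_extents(rect)
  expect_equal(ax2$longest_um, sqrt(50^2 + 20^2), tolerance = 1e-9)
  expect_equal(ax2$shortest_um, 20, tolerance = 1e-9)

  ax3 <- axis_extents(rect, mode = "3D")
  expect_equal(ax3$longest_um, sqrt(2900), tolerance = 1e-9)
  expect_gte(ax3$longest_um, ax3$shortest_um)

  expect_error(axis_extents(two[1, ]), "2 nodes")
})

test_that("generated morphologies report extents within 1%", {
  rec <- generate_morphology(morph_spec(271.43, 148.60), seed = 3)
  ax <- axis_extents(rec)
  expect_equal(ax$longest_um, 271.43, tolerance = 0.01)
  expect_equal(ax$shortest_um, 148.60, tolerance = 0.01)
  expect_gte(ax$longest_um, ax$shortest_um)
})

test_that("convex hull metrics match closed forms and the brute-force oracle", {
  cube <- tibble::tibble(
    id = 1:8, type = 3L,
    x = c(0, 1, 0, 1, 0, 1, 0, 1), y = c(0, 0, 1, 1, 0, 0, 1, 1),
    z = c(0, 0, 0, 0, 1, 1, 1, 1), radius = 1,
    parent = c(-1L, rep(1L, 7))
  )
  m <- convex_hull_metrics(cube)
  expect_equal(m$volume_um3, 1, tolerance = 1e-12)
  expect_equal(m$surface_area_um2, 6, tolerance = 1e-12)

  simplex <- tibble::tibble(
    id = 1:4, type = 3L, x = c(0, 1, 0, 0), y = c(0, 0, 1, 0),
    z = c(0, 0, 0, 1), radius = 1, parent = c(-1L, 1L, 1L, 1L)
  )
  ms <- convex_hull_metrics(simplex)
  expect_equal(ms$volume_um3, 1 / 6, tolerance = 1e-12)
  expect_equal(ms$surface_area_um2, 1.5 + sqrt(3) / 2, tolerance = 1e-12)

  set.seed(12)
  p <- matrix(rnorm(90), 30, 3)
  rnd <- tibble::tibble(id = 1:30, type = 3L, x = p[, 1], y = p[, 2],
                        z = p[, 3], radius = 1,
                        parent = c(-1L, rep(1L, 29)))
  mr <- convex_hull_metrics(rnd)
  oracle <- oracle_hull_metrics(p)
  expect_equal(mr$volume_um3, oracle[["volume"]], tolerance = 1e-9)
  expect_equal(mr$surface_area_um2, oracle[["area"]], tolerance = 1e-9)
})

test_that("hull metrics are invariant under rigid motion and flag coplanar sets", {
  set.seed(13)
  p <- matrix(rnorm(60), 20, 3)
  rnd <- tibble::tibble(id = 1:20, type = 3L, x = p[, 1], y = p[, 2],
                        z = p[, 3], radius = 1,
                        parent = c(-1L, rep(1L, 19)))
  m0 <- convex_hull_metrics(rnd)
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  pr <- p %*% rot
  moved <- rnd
  moved$x <- pr[, 1] + 50
  moved$y <- pr[, 2] - 20
  moved$z <- pr[, 3] + 5
  m1 <- convex_hull_metrics(moved)
  expect_equal(m1$volume_um3, m0$volume_um3, tolerance = 1e-6)
  expect_equal(m1$surface_area_um2, m0$surface_area_um2, tolerance = 1e-6)

  flat <- tibble::tibble(id = 1:4, type = 3L, x = c(0, 1, 0, 1),
                         y = c(0, 0, 1, 1), z = 0, radius = 1,
                         parent = c(-1L, 1L, 1L, 1L))
  mf <- convex_hull_metrics(flat)
  expect_true(mf$degenerate)
  expect_equal(mf$volume_um3, 0)
  expect_equal(mf$surface_area_um2, 1, tolerance = 1e-9)
})

test_that("Sholl profiles match closed forms and the dense oracle", {
  prof <- sholl(straight_neurite(100), step = 10)
  expect_true(all(prof$crossings[prof$radius_um <= 90] == 1))
  expect_true(all(prof$crossings[prof$radius_um >= 100] == 0))

  yt <- sholl(y_tree(branch_at = 25), step = 10)
  expect_true(all(yt$crossings[yt$radius_um <= 20] == 1))
  expect_true(all(yt$crossings[yt$radius_um %in% c(30, 40, 50)] >= 2))

  rec <- generate_morphology(morph_spec(300, 200), seed = 14)
  prof2 <- sholl(rec, step = 10)
  oracle <- oracle_sholl(rec, step = 10)
  expect_equal(prof2$crossings, oracle$crossings)
  expect_equal(sum(prof2$crossings), sum(oracle$crossings))

  expect_error(sholl(rec, step = 0), "positive")
})

test_that("the K-S comparison matches the exhaustive ECDF oracle", {
  same <- tibble::tibble(radius_um = c(10, 20, 30), crossings = c(2L, 3L, 1L))
  r0 <- ks_two_sample(same, same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  a <- tibble::tibble(radius_um = c(10, 20), crossings = c(3L, 3L))
  b <- tibble::tibble(radius_um = c(50, 60), crossings = c(2L, 4L))
  expect_equal(ks_two_sample(a, b)$statistic, 1)

  set.seed(15)
  x <- sample(1:40, 10, TRUE)
  y <- sample(10:60, 10, TRUE)
  d_pkg <- ks_two_sample(x, y)$statistic
  grid <- sort(unique(c(x, y)))
  d_hand <- max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g),
                           numeric(1))))
  expect_equal(d_pkg, d_hand, tolerance = 1e-12)

  expect_error(ks_two_sample(numeric(), y), "empty")
})

test_that("proximal-heavy and distal-heavy trees differ by Sholl K-S", {
  prox <- generate_morphology(morph_spec(271.43, 148.6, branch_depth = 10),
                              seed = 16)
  dist <- generate_morphology(
    morph_spec(237.03, 79.73, branch_radial_profile = "distal-heavy",
               branch_depth = 10),
    seed = 17
  )
  r <- ks_two_sample(sholl(prox, 10), sholl(dist, 10))
  expect_lt(r$p_value, 0.05)
})
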