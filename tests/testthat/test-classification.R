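# K-means classification, WCSS/elbow model selection, separation accuracy.

fake_profiles <- function(m, labels = NULL) {
  out <- tibble::tibble(
    cell_id = sprintf("c%02d", seq_len(nrow(m))),
    ap_halfwidth_ms = m[, 1], ahp_mv = m[, 2], rin_mohm = m[, 3]
  )
  if (!is.null(labels)) out$label <- labels
  out
}

test_that("matrix assembly excludes incomplete rows and records the transform", {
  m <- cbind(c(0.3, 0.5, NA, 0.4), c(4, 2, 3, 1), c(100, 300, 200, 150))
  pr <- fake_profiles(m)
  expect_message(asm <- assemble_matrix(pr), "c03")
  expect_equal(rownames(asm$matrix), c("c01", "c02", "c04"))
  expect_equal(asm$excluded, "c03")
  expect_equal(unname(colMeans(asm$matrix)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(asm$matrix, 2, sd)), rep(1, 3), tolerance = 1e-12)

  # Round trip: standardized centroids map back to original units.
  fit <- kmeans_partition(asm, 1, restarts = 2, seed = 1)
  expect_equal(unname(fit$centers_original[1, ]),
               unname(colMeans(m[c(1, 2, 4), ])), tolerance = 1e-10)

  expect_error(assemble_matrix(fake_profiles(m[3, , drop = FALSE])),
               "fewer than 2")
})

test_that("best-of-restarts WCSS matches the exhaustive-partition optimum", {
  for (seed in 1:3) {
    set.seed(seed * 100)
    m <- matrix(rnorm(8 * 3), 8, 3)
    rownames(m) <- sprintf("r%d", 1:8)
    fit <- kmeans_partition(m, 2, restarts = 30, seed = seed)
    expect_equal(fit$wcss, oracle_min_wcss(m, 2), tolerance = 1e-8)
  }
  set.seed(42)
  m3 <- matrix(rnorm(7 * 2), 7, 2)
  rownames(m3) <- sprintf("r%d", 1:7)
  fit3 <- kmeans_partition(m3, 3, restarts = 60, seed = 1)
  expect_equal(fit3$wcss, oracle_min_wcss(m3, 3), tolerance = 1e-8)
})

test_that("clustering is invariant to row order and per-column rescaling", {
  set.seed(5)
  m <- rbind(matrix(rnorm(15, 0), 5, 3), matrix(rnorm(15, 4), 5, 3))
  rownames(m) <- sprintf("r%02d", 1:10)
  f1 <- kmeans_partition(m, 2, restarts = 20, seed = 2)
  perm <- sample(10)
  f2 <- kmeans_partition(m[perm, ], 2, restarts = 20, seed = 7)
  expect_equal(f1$wcss, f2$wcss, tolerance = 1e-9)
  expect_equal(f1$assignments[rownames(m)[perm]], f2$assignments)

  pr <- fake_profiles(m)
  a1 <- kmeans_partition(assemble_matrix(pr), 2, restarts = 20, seed = 3)
  pr_scaled <- pr
  pr_scaled$rin_mohm <- pr_scaled$rin_mohm * 50 + 7
  a2 <- kmeans_partition(assemble_matrix(pr_scaled), 2, restarts = 20,
                         seed = 3)
  expect_equal(a1$assignments, a2$assignments)
})

test_that("degenerate inputs are handled", {
  m <- matrix(1, 5, 3)
  rownames(m) <- sprintf("r%d", 1:5)
  fit <- kmeans_partition(m, 1, restarts = 3, seed = 1)
  expect_equal(fit$wcss, 0)
  expect_error(kmeans_partition(m, 6), "exceeds")
  expect_error(kmeans_partition(m, 0), "at least 1")
})

test_that("the WCSS curve is monotone non-increasing", {
  set.seed(8)
  m <- matrix(rnorm(60), 20, 3)
  rownames(m) <- sprintf("r%02d", 1:20)
  curve <- wcss_curve(m, k_max = 6, restarts = 15, seed = 4)
  expect_true(all(diff(curve$wcss) <= 1e-9))

  ident <- matrix(2, 6, 3)
  rownames(ident) <- sprintf("r%d", 1:6)
  ci <- wcss_curve(ident, k_max = 3, restarts = 3, seed = 1)
  expect_equal(ci$wcss, rep(0, 3))

  expect_warning(wcss_curve(m, k_max = 30, restarts = 3, seed = 1),
                 "truncating")
})

test_that("the elbow rule maximizes the second difference", {
  # Second differences of (100, 20, 18, 17): 78 at K = 2, 1 at K = 3.
  expect_equal(choose_k_elbow(tibble::tibble(k = 1:4,
                                             wcss = c(100, 20, 18, 17))), 2)
  # Linear curve: all second differences zero; tie broken toward smaller K.
  expect_equal(choose_k_elbow(tibble::tibble(k = 1:5, wcss = 50 - 10 * (1:5))),
               2)
  expect_error(choose_k_elbow(tibble::tibble(k = 1:2, wcss = c(2, 1))),
               "at least 3")

  # Two well-separated clouds select K = 2.
  set.seed(9)
  m <- rbind(matrix(rnorm(30, 0, 0.3), 10, 3), matrix(rnorm(30, 5, 0.3), 10, 3))
  rownames(m) <- sprintf("r%02d", 1:20)
  curve <- wcss_curve(m, k_max = 6, restarts = 15, seed = 2)
  expect_equal(choose_k_elbow(curve), 2)
})

test_that("three separated clouds produce a WCSS drop through K = 3", {
  set.seed(10)
  m <- rbind(matrix(rnorm(24, 0, 0.2), 8, 3), matrix(rnorm(24, 5, 0.2), 8, 3),
             matrix(rnorm(24, 10, 0.2), 8, 3))
  rownames(m) <- sprintf("r%02d", 1:24)
  curve <- wcss_curve(m, k_max = 6, restarts = 20, seed = 3)
  w <- curve$wcss
  expect_gt(w[2] / w[3], 5)   # large drop to K = 3
  expect_lt(w[3] / w[5], 3)   # flat afterwards
  # The second-difference elbow lands on one of the two sharp corners.
  expect_true(choose_k_elbow(curve) %in% c(2, 3))
})

test_that("separation accuracy maps clusters to majority labels", {
  # 11 of 12 D-stellate cells in the D-majority cluster: 91.7%.
  cl <- setNames(c(rep(1, 11), 2, rep(2, 20)), sprintf("c%02d", 1:32))
  labs <- setNames(c(rep("D_stellate", 12), rep("small", 20)),
                   sprintf("c%02d", 1:32))
  acc <- separation_accuracy(cl, labs)
  expect_equal(acc$accuracy[acc$label == "D_stellate"], 11 / 12,
               tolerance = 1e-12)
  expect_equal(round(100 * acc$accuracy[acc$label == "D_stellate"], 1), 91.7)
  expect_equal(acc$accuracy[acc$label == "small"], 1)

  perfect <- separation_accuracy(setNames(c(1, 1, 2, 2), letters[1:4]),
                                 setNames(c("a", "a", "b", "b"), letters[1:4]))
  expect_true(all(perfect$accuracy == 1))

  expect_error(separation_accuracy(cl, NULL), "labels")

  # Random balanced assignment scores near chance.
  set.seed(11)
  accs <- replicate(200, {
    cl_r <- setNames(sample(1:2, 40, TRUE), sprintf("c%02d", 1:40))
    labs_r <- setNames(rep(c("a", "b"), each = 20), sprintf("c%02d", 1:40))
    mean(separation_accuracy(cl_r, labs_r)$accuracy)
  })
  expect_gt(mean(accs), 0.45)
  expect_lt(mean(accs), 0.65)
})

test_that("populations drawn at the published means separate almost perfectly", {
  accs <- sapply(1:5, function(s) {
    pop <- sample_feature_population(preset_feature_groups(50, 50), seed = s)
    fit <- kmeans_partition(assemble_matrix(pop), 2, restarts = 25,
                            seed = s)
    mean(separation_accuracy(fit)$accuracy)
  })
  expect_gte(mean(accs), 0.99)

  # Nearly-degenerate spread: recovery is exact.
  pop <- sample_feature_population(preset_feature_groups(50, 50, sd_scale = 0.05),
                                   seed = 1)
  fit <- kmeans_partition(assemble_matrix(pop), 2, restarts = 10, seed = 1)
  expect_equal(mean(separation_accuracy(fit)$accuracy), 1)

  # Identical group means: accuracy falls to chance.
  g <- preset_feature_groups(40, 40)
  g[2, 3:8] <- g[1, 3:8]
  pop2 <- sample_feature_population(g, seed = 2)
  fit2 <- kmeans_partition(assemble_matrix(pop2), 2, restarts = 10, seed = 2)
  expect_lt(mean(separation_accuracy(fit2)$accuracy), 0.75)
})

test_that("tidiers summarize partitions", {
  pop <- sample_feature_population(preset_feature_groups(12, 12), seed = 3)
  fit <- kmeans_partition(assemble_matrix(pop), 2, restarts = 10, seed = 3)
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_true(all(c("cluster", "size", "rin_mohm") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_equal(gl$n, 24)
})
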