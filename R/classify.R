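# K-means classification of intrinsic properties with elbow-method model
# selection, following the three-feature scheme (AP halfwidth, AHP metric,
# input resistance) used to separate D-stellate from small glycinergic
# cells.

FEATURE_COLS <- c("ap_halfwidth_ms", "ahp_mv", "rin_mohm")

#' Assemble the clustering feature matrix
#'
#' Selects the three classification features, drops rows with any missing
#' feature (reporting them), and optionally z-scores each column, recording
#' the transform so centroids can be mapped back to original units.
#'
#' @param profiles Data frame with columns `cell_id`, `ap_halfwidth_ms`,
#'   `ahp_mv`, `rin_mohm` and optionally `label` (e.g. from
#'   [build_intrinsic_profile()] or [sample_feature_population()]).
#' @param standardize Z-score each feature column. Raw input resistance
#'   (hundreds of MOhm) would otherwise dominate the Euclidean metric.
#' @return List with `matrix` (numeric, rownames = cell ids), `center`,
#'   `scale`, `excluded` (cell ids dropped for missing features) and
#'   `labels` (named character or `NULL`).
#' @export
assemble_matrix <- function(profiles, standardize = TRUE) {
  miss <- setdiff(c("cell_id", FEATURE_COLS), names(profiles))
  if (length(miss) > 0) {
    abort(paste("`profiles` is missing columns:", paste(miss, collapse = ", ")))
  }
  x <- as.matrix(profiles[, FEATURE_COLS])
  rownames(x) <- profiles$cell_id
  complete <- stats::complete.cases(x)
  excluded <- profiles$cell_id[!complete]
  if (length(excluded) > 0) {
    inform(paste("excluding rows with missing features:",
                 paste(excluded, collapse = ", ")))
  }
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 2) abort("fewer than 2 complete rows; cannot cluster")
  center <- rep(0, ncol(x))
  scl <- rep(1, ncol(x))
  if (standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2, center), 2, scl, "/")
  }
  labels <- NULL
  if ("label" %in% names(profiles)) {
    labels <- setNames(as.character(profiles$label), profiles$cell_id)[
      rownames(x)]
  }
  list(matrix = x, center = setNames(center, FEATURE_COLS),
       scale = setNames(scl, FEATURE_COLS), excluded = excluded,
       labels = labels)
}

# Map standardized-space centroids back to original units.
unstandardize <- function(centers, center, scale) {
  sweep(sweep(centers, 2, scale, "*"), 2, center, "+")
}

# k-means++-style seeding: first centre uniform, later centres with
# probability proportional to squared distance from the nearest centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[j] <- sample.int(n, 1, prob = p)
      d2j <- rowSums((x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, d2j)
    }
  }
  x[idx, , drop = FALSE]
}

run_lloyd <- function(x, centers) {
  tryCatch(
    suppressWarnings(
      kmeans(x, centers = centers, iter.max = 300, algorithm = "Lloyd")
    ),
    error = function(e) NULL  # duplicate/empty-cluster starts are skipped
  )
}

# Degenerate fallback when every Lloyd start fails (e.g. fewer distinct
# points than k): assign each row to the nearest of the distinct rows.
degenerate_fit <- function(m, k) {
  u <- unique(m)
  cen <- u[pmin(seq_len(k), nrow(u)), , drop = FALSE]
  d2 <- vapply(seq_len(nrow(cen)), function(j) {
    rowSums((m - matrix(cen[j, ], nrow(m), ncol(m), byrow = TRUE))^2)
  }, numeric(nrow(m)))
  cl <- max.col(-d2, ties.method = "first")
  list(cluster = cl, centers = cen,
       withinss = vapply(seq_len(k), function(j) {
         sum(d2[cl == j, j])
       }, numeric(1)),
       size = tabulate(cl, k))
}

#' K-means partition of the feature matrix
#'
#' Lloyd iterations from k-means++-style seeding, best of `restarts` runs by
#' within-cluster sum of squares (WCSS). Clusters are relabelled in order of
#' decreasing size for reproducibility.
#'
#' @param x Feature matrix, or the list returned by [assemble_matrix()].
#' @param k Number of clusters.
#' @param restarts Independent seeded runs.
#' @param seed Integer seed.
#' @param warm_start Optional centre matrix included as an extra restart.
#' @return Object of class `stellate_kmeans`: list with `k`, `assignments`
#'   (named integer, 1..k), `centers` (standardized space),
#'   `centers_original` (original units when the transform is known),
#'   `wcss`, `sizes`, `restarts`, `seed`.
#' @export
kmeans_partition <- function(x, k, restarts = 50, seed = NULL,
                             warm_start = NULL) {
  asm <- if (is.list(x) && !is.null(x$matrix)) x else list(matrix = as.matrix(x))
  m <- asm$matrix
  if (k < 1) abort("`k` must be at least 1")
  if (k > nrow(m)) abort("`k` exceeds the number of rows")
  new_seeded_rng(seed)
  best <- NULL
  starts <- c(lapply(seq_len(restarts), function(i) kmeanspp_centers(m, k)),
              if (!is.null(warm_start)) list(warm_start))
  for (cen in starts) {
    fit <- run_lloyd(m, cen)
    if (!is.null(fit) &&
        (is.null(best) || sum(fit$withinss) < sum(best$withinss))) {
      best <- fit
    }
  }
  if (is.null(best)) best <- degenerate_fit(m, k)
  ord <- order(-best$size, best$centers[, 1])
  relabel <- match(seq_len(k), ord)
  assignments <- setNames(relabel[best$cluster], rownames(m))
  centers <- best$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  centers_original <- if (!is.null(asm$center)) {
    unstandardize(centers, asm$center, asm$scale)
  } else NULL
  structure(
    list(k = k, assignments = assignments, centers = centers,
         centers_original = centers_original,
         wcss = sum(best$withinss), sizes = tabulate(assignments, k),
         restarts = restarts, seed = seed, labels = asm$labels),
    class = "stellate_kmeans"
  )
}

#' @export
print.stellate_kmeans <- function(x, ...) {
  cat(sprintf("K-means partition: k = %d, n = %d, WCSS = %.4g\n",
              x$k, length(x$assignments), x$wcss))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' WCSS curve over candidate cluster counts
#'
#' Best-of-restarts WCSS for K = 1..`k_max`. Each K receives, in addition to
#' its random restarts, a warm start built from the K-1 solution (previous
#' centroids plus the worst-fitting point), which makes the curve
#' non-increasing by construction.
#'
#' @inheritParams kmeans_partition
#' @param k_max Largest K scanned; truncated (with a warning) at the row
#'   count.
#' @return Tibble with columns `k` and `wcss`, of class `stellate_wcss`.
#' @export
wcss_curve <- function(x, k_max = 8, restarts = 50, seed = NULL) {
  asm <- if (is.list(x) && !is.null(x$matrix)) x else list(matrix = as.matrix(x))
  m <- asm$matrix
  if (k_max > nrow(m)) {
    warn(sprintf("k_max = %d exceeds n = %d; truncating", k_max, nrow(m)))
    k_max <- nrow(m)
  }
  new_seeded_rng(seed)
  wcss <- numeric(k_max)
  prev <- NULL
  for (k in seq_len(k_max)) {
    warm <- NULL
    if (!is.null(prev)) {
      d2 <- rowSums((m - prev$centers[prev$assignments, , drop = FALSE])^2)
      warm <- rbind(prev$centers, m[which.max(d2), , drop = FALSE])
    }
    fit <- kmeans_partition(asm, k, restarts = restarts, warm_start = warm)
    wcss[k] <- fit$wcss
    prev <- fit
  }
  structure(tibble(k = seq_len(k_max), wcss = wcss),
            class = c("stellate_wcss", class(tibble())))
}

#' Choose K by the elbow of the WCSS curve
#'
#' Picks the interior K maximizing the discrete second difference
#' `WCSS(K-1) - 2 WCSS(K) + WCSS(K+1)`; ties break toward smaller K.
#'
#' @param curve Tibble from [wcss_curve()] (columns `k`, `wcss`).
#' @return The selected K.
#' @export
choose_k_elbow <- function(curve) {
  if (nrow(curve) < 3) abort("WCSS curve needs at least 3 points")
  curve <- arrange(curve, .data$k)
  w <- curve$wcss
  sec <- w[1:(length(w) - 2)] - 2 * w[2:(length(w) - 1)] + w[3:length(w)]
  curve$k[which.max(sec) + 1L]
}

#' Per-label separation accuracy of a partition
#'
#' Maps each cluster to its majority label (several clusters may map to the
#' same label when K exceeds the label count) and reports, per label, the
#' fraction of its cells assigned to a cluster mapped to that label —
#' the score under which the published partition separated 11/12 (91.7%) of
#' visually identified D-stellate cells.
#'
#' @param assignment A `stellate_kmeans` object (or named cluster vector).
#' @param labels Named character vector of true labels (names = cell ids);
#'   defaults to labels carried by the assignment.
#' @return Tibble with `label`, `n`, `n_correct`, `accuracy`, plus the
#'   cluster-to-label `mapping` as an attribute.
#' @export
separation_accuracy <- function(assignment, labels = NULL) {
  cl <- if (inherits(assignment, "stellate_kmeans")) {
    assignment$assignments
  } else assignment
  labels <- labels %||%
    (if (inherits(assignment, "stellate_kmeans")) assignment$labels)
  if (is.null(labels) || length(labels) == 0) abort("labels are required")
  labels <- labels[names(cl)]
  if (anyNA(labels)) abort("labels must cover all assigned cells")
  mapping <- vapply(split(labels, cl), function(l) {
    names(sort(table(l), decreasing = TRUE))[1]
  }, character(1))
  predicted <- mapping[as.character(cl)]
  out <- tibble(label = labels, correct = predicted == labels) |>
    group_by(.data$label) |>
    summarise(n = n(), n_correct = sum(.data$correct),
              accuracy = mean(.data$correct), .groups = "drop")
  attr(out, "mapping") <- mapping
  out
}
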