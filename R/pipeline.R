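# End-to-end synthetic pipeline: generate -> extract -> classify -> report.

#' Default pipeline configuration
#'
#' @param seed Master seed; per-cell seeds are derived from it.
#' @param n_per_class Simulated cells per phenotype.
#' @param sampling_khz Sweep sampling rate (kHz).
#' @param k Clusters for the partition stage.
#' @param restarts K-means restarts.
#' @param feature_jitter Fractional SD applied to each cell's true feature
#'   parameters so the population has biological spread.
#' @return Named list of class `stellate_config`.
#' @export
pipeline_config <- function(seed = 1, n_per_class = 6, sampling_khz = 20,
                            k = 2, restarts = 25, feature_jitter = 0.04) {
  cfg <- list(seed = seed, n_per_class = n_per_class,
              sampling_khz = sampling_khz, k = k, restarts = restarts,
              feature_jitter = feature_jitter)
  validate_config(cfg)
  structure(cfg, class = "stellate_config")
}

validate_config <- function(cfg) {
  problems <- character()
  req <- c("seed", "n_per_class", "sampling_khz", "k", "restarts",
           "feature_jitter")
  miss <- setdiff(req, names(cfg))
  if (length(miss) > 0) {
    problems <- c(problems, paste("missing keys:", paste(miss, collapse = ", ")))
  }
  for (key in intersect(req, names(cfg))) {
    x <- cfg[[key]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      problems <- c(problems, sprintf("`%s` must be a single finite number", key))
    }
  }
  if (length(problems) > 0) {
    abort(paste0("invalid pipeline config:\n", paste("-", problems,
                                                     collapse = "\n")))
  }
  invisible(cfg)
}

#' Run the synthetic analysis pipeline end to end
#'
#' Simulates a population of D-stellate and small (L-stellate) cells around
#' the published phenotype means, extracts each cell's intrinsic profile
#' from its sweeps, clusters the three classification features, and scores
#' separation accuracy against the generating labels.
#'
#' @param config A [pipeline_config()] (or a plain list with the same keys).
#' @param out_dir Optional directory; when given, profiles, assignments and
#'   a JSON summary are written there.
#' @return List of class `stellate_pipeline`: `profiles`, `clusters`,
#'   `wcss`, `accuracy`, `summary` (named list with seeds and per-class
#'   means).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  validate_config(config)
  protocol <- step_protocol(
    step_amplitudes = c(-300, 100, 200, 500),
    sampling_khz = config$sampling_khz
  )
  classes <- c("D_stellate", "L_small")
  profiles <- list()
  for (ci in seq_along(classes)) {
    base <- phenotype_preset(classes[ci])
    for (j in seq_len(config$n_per_class)) {
      cell_seed <- config$seed + 1000 * ci + j
      set.seed(cell_seed)
      jit <- function(x) x * (1 + rnorm(1, 0, config$feature_jitter))
      phen <- phenotype_preset(
        classes[ci],
        r_in_true = jit(base$r_in_true),
        halfwidth_true = min(max(jit(base$halfwidth_true), 0.2), 1.2),
        ahp_metric_true = max(jit(base$ahp_metric_true), 0.2)
      )
      sweeps <- simulate_step_responses(phen, protocol, seed = cell_seed,
                                        jitter_growth = 0)
      pr <- build_intrinsic_profile(
        sweeps, cell_id = sprintf("%s_%02d", classes[ci], j)
      )
      pr$label <- classes[ci]
      profiles[[length(profiles) + 1L]] <- pr
    }
  }
  profiles <- bind_rows(profiles)

  asm <- assemble_matrix(profiles)
  clusters <- kmeans_partition(asm, k = config$k,
                               restarts = config$restarts,
                               seed = config$seed)
  curve <- wcss_curve(asm, k_max = min(6, nrow(asm$matrix)),
                      restarts = config$restarts, seed = config$seed)
  accuracy <- separation_accuracy(clusters)

  summary <- list(
    seed = config$seed,
    n_cells = nrow(profiles),
    classes = as.list(setNames(
      map_dbl(classes, function(cl) sum(profiles$label == cl)), classes
    )),
    k = config$k,
    wcss = clusters$wcss,
    elbow_k = choose_k_elbow(curve),
    accuracy = as.list(setNames(accuracy$accuracy, accuracy$label)),
    mean_rin_mohm = as.list(setNames(
      map_dbl(classes, function(cl) {
        mean(profiles$rin_mohm[profiles$label == cl], na.rm = TRUE)
      }), classes
    ))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(profiles, file.path(out_dir, "intrinsic_profiles.csv"))
    readr::write_csv(
      tibble(cell_id = names(clusters$assignments),
             cluster = clusters$assignments),
      file.path(out_dir, "cluster_assignments.csv")
    )
    readr::write_csv(as_tibble(curve), file.path(out_dir, "wcss_curve.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(
    list(profiles = profiles, clusters = clusters, wcss = curve,
         accuracy = accuracy, summary = summary),
    class = "stellate_pipeline"
  )
}

#' @export
print.stellate_pipeline <- function(x, ...) {
  cat(sprintf("pipeline: %d cells, k = %d, elbow k = %d, WCSS = %.3g\n",
              x$summary$n_cells, x$summary$k, x$summary$elbow_k,
              x$summary$wcss))
  print(x$accuracy)
  invisible(x)
}
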