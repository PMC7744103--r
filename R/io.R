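# Delimited-text sweep container: one long CSV of samples plus a JSON
# sidecar holding protocol metadata and (optionally) generator ground truth.

#' Write / read a sweep set as delimited text
#'
#' The CSV holds the long sample table (`sweep`, `step_pa`, `time_ms`,
#' `voltage_mv`, `current_pa`); `<path>.json` holds `cell_id`,
#' `sampling_khz`, `onset_ms`, `offset_ms` and, for synthetic data, the
#' ground-truth spike times.
#'
#' @param sweepset Long sweep tibble (e.g. from
#'   [simulate_step_responses()]).
#' @param path CSV path; the JSON sidecar is written next to it.
#' @param ground_truth Include generator ground truth in the sidecar.
#' @return `write_sweep_set()`: the path, invisibly; `read_sweep_set()`:
#'   the sweep tibble with its attributes restored.
#' @export
write_sweep_set <- function(sweepset, path, ground_truth = TRUE) {
  readr::write_csv(as_tibble(sweepset), path)
  meta <- list(
    cell_id = attr(sweepset, "cell_id"),
    sampling_khz = attr(sweepset, "sampling_khz"),
    onset_ms = attr(sweepset, "onset_ms"),
    offset_ms = attr(sweepset, "offset_ms")
  )
  gt <- attr(sweepset, "ground_truth")
  if (ground_truth && !is.null(gt)) meta$ground_truth <- gt
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (a in c("cell_id", "sampling_khz", "onset_ms", "offset_ms")) {
      attr(out, a) <- meta[[a]]
    }
    if (!is.null(meta$ground_truth)) {
      attr(out, "ground_truth") <- as_tibble(meta$ground_truth)
    }
  }
  out
}

#' Write / read a single trace as delimited text
#'
#' @param trace Tibble with `time_ms` and a signal column.
#' @param path CSV path.
#' @return The path / the trace tibble.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  attr(out, "sampling_khz") <- 1 / grid_dt(out$time_ms)
  out
}
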