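#' Write / read a trace set as CSV with a ground-truth sidecar
#'
#' The CSV holds the long trace table (`cell_id`, `population`, `repeat`,
#' `pulse_index`, `time_s`, `fm_value`); simulation ground truth, pulse
#' times and the seed travel in a JSON sidecar (`<path>.json`) when
#' available.
#'
#' @param trace_set An `npq_trace_set` or a long trace tibble.
#' @param path CSV file path.
#' @param sidecar Whether to write the JSON sidecar (trace sets only).
#' @return `write_trace_csv()` returns `path` invisibly;
#'   `read_trace_csv()` an `npq_trace_set` (ground truth present only if a
#'   sidecar is found).
#' @export
write_trace_csv <- function(trace_set, path, sidecar = TRUE) {
  df <- if (inherits(trace_set, "npq_trace_set")) trace_set$traces else trace_set
  utils::write.csv(df, path, row.names = FALSE)
  if (sidecar && inherits(trace_set, "npq_trace_set")) {
    meta <- list(
      ground_truth = trace_set$ground_truth,
      pulse_times = trace_set$pulse_times,
      label = trace_set$label,
      seed = trace_set$seed,
      repeat_index = trace_set$repeat_index
    )
    jsonlite::write_json(meta, paste0(path, ".json"), digits = I(17),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  df$cell_id <- as.character(df$cell_id)
  side <- paste0(path, ".json")
  gt <- NULL; ptimes <- sort(unique(df$time_s)); label <- df$population[1]
  seed <- NA_integer_; rep_index <- df$`repeat`[1]
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    gt <- tibble::as_tibble(meta$ground_truth)
    ptimes <- meta$pulse_times
    label <- meta$label
    seed <- meta$seed
    rep_index <- meta$repeat_index
  }
  structure(
    list(traces = df, ground_truth = gt, pulse_times = ptimes,
         label = label, seed = seed, repeat_index = rep_index),
    class = "npq_trace_set"
  )
}

#' Write a score set as CSV
#'
#' @param scores Score tibble from [score_traces()].
#' @param path CSV file path.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
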