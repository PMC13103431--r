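#' Scatter of cells in a plane of the NPQ score space
#'
#' @param scores Score tibble from [score_traces()].
#' @param axes Character pair of score columns to plot.
#' @param trend Optional trend tibble from [affine_trend()] to overlay.
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, axes = c("qT_score", "qE_score"),
                        trend = NULL) {
  p <- ggplot2::ggplot(scores,
         ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]])) +
    ggplot2::geom_point(ggplot2::aes(colour = if ("population" %in% names(scores))
      .data$population else NULL), alpha = 0.6, size = 0.8) +
    ggplot2::labs(colour = "population") +
    ggplot2::theme_minimal()
  if (!is.null(trend)) {
    p <- p + ggplot2::geom_abline(slope = trend$slope,
                                  intercept = trend$intercept,
                                  linewidth = 0.4, colour = "black")
  }
  p
}

#' @export
autoplot.npq_dictionary <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
      ggplot2::aes(x = .data$pulse_index, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~atom, scales = "free_y") +
    ggplot2::labs(x = "pulse index", y = "atom value") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.npq_repeat_distance <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(distance = object$D_ii, kind = "same cell (D_ii)"),
    tibble::tibble(distance = object$D_ij, kind = "cell to population (D_ij)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, fill = .data$kind)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, alpha = 0.6, position = "identity") +
    ggplot2::labs(x = "distance in NPQ space", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.npq_grid_traces <- function(object, ...) {
  df <- object |>
    dplyr::filter(!purrr::map_lgl(.data$mean_trace, is.null)) |>
    tidyr::unnest_longer(col = "mean_trace", indices_to = "pulse_index",
                         values_to = "fm") |>
    dplyr::mutate(box = paste0("(", .data$ix, ",", .data$iy, ")"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pulse_index, y = .data$fm,
                                   group = .data$box)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(-.data$iy),
                        cols = ggplot2::vars(.data$ix)) +
    ggplot2::labs(x = "pulse index", y = "Fm' (initial-normalized)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text = ggplot2::element_blank())
}

#' Plot simulated or extracted Fm' traces
#'
#' @param traces An `npq_trace_set` or long trace tibble.
#' @param normalize If `TRUE`, traces are normalized to their initial value.
#' @param max_cells Plot at most this many cells (first by id).
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, normalize = TRUE, max_cells = 50) {
  df <- if (inherits(traces, "npq_trace_set")) traces$traces else traces
  keep <- utils::head(unique(df$cell_id), max_cells)
  df <- dplyr::filter(df, .data$cell_id %in% keep)
  if (normalize) {
    df <- df |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::mutate(fm_value = .data$fm_value /
                      .data$fm_value[.data$pulse_index == 1]) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$fm_value,
                                   group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = if (normalize) "Fm' / Fm'(0)" else "Fm' (a.u.)") +
    ggplot2::theme_minimal()
}
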