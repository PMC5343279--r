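#' Heat map of a chromatin-context matrix
#'
#' @param object A `context_matrix` from [context_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.context_matrix <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$mark, y = .data$category,
                               fill = .data$mean_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean score",
                  title = "Chromatin-mark scores by peak category") +
    ggplot2::theme_minimal()
}

#' Line plot of a sliding-window profile
#'
#' @param object A `window_profile` from [sliding_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$midpoint, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window midpoint (bp)", y = "window mean") +
    ggplot2::theme_minimal()
}

#' Box-style summary plot of SOCE metrics by condition
#'
#' Median and quartiles per condition, faceted by metric — the summary
#' behind calcium-imaging box plots.
#'
#' @param object A `soce_summary` from [cohort_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.soce_summary <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$condition, y = .data$median)) +
    ggplot2::geom_crossbar(ggplot2::aes(ymin = .data$q25,
                                        ymax = .data$q75),
                           width = 0.5) +
    ggplot2::geom_point(ggplot2::aes(y = .data$min), shape = 4) +
    ggplot2::geom_point(ggplot2::aes(y = .data$max), shape = 4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of peak-midpoint distances to the closest TSS
#'
#' @param annotations A `peak_annotation` tibble.
#' @param binwidth Bin width in bp.
#' @return A ggplot object.
#' @export
plot_tss_distances <- function(annotations, binwidth = 500) {
  h <- tss_distance_histogram(annotations, binwidth = binwidth)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = binwidth) +
    ggplot2::labs(x = "distance to closest TSS (bp)", y = "peaks") +
    ggplot2::theme_minimal()
}

#' Normalized calcium traces with protocol events
#'
#' Plots delta-F/F0 per cell, colored by condition, with vertical lines at
#' the thapsigargin and calcium re-addition times.
#'
#' @param traces Long trace tibble (see [read_traces()]).
#' @param tg_time,ca_time Protocol event times in seconds.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, tg_time, ca_time) {
  norm <- traces |>
    dplyr::group_by(.data$condition, .data$cell_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::mutate(dff = normalize_trace(.data$raw, .data$background)) |>
    dplyr::ungroup()
  ggplot2::ggplot(norm, ggplot2::aes(x = .data$time_s, y = .data$dff,
                                     group = .data$cell_id,
                                     colour = .data$condition)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = c(tg_time, ca_time),
                        linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F[0])) +
    ggplot2::theme_minimal()
}
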