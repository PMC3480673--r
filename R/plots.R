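# ggplot2 displays for sweep reports, strain traces and activation maps.

#' Column map of CURE versus interventricular delay per LV site
#'
#' The sweep analogue of the clinical CURE-vs-VVD column map: one column
#' per (site, VVD) configuration, grouped by LV pacing site.
#'
#' @param object a `sync_report` from [run_sweep()].
#' @param metric column to display (default `"cure"`).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sync_report <- function(object, metric = "cure", ...) {
  df <- tibble::as_tibble(object)
  df <- dplyr::filter(df, .data$status == "ok")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$vvd_ms),
                                   y = .data[[metric]],
                                   fill = .data$lv_site)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = "VV delay (ms), positive = LV first",
                  y = toupper(metric), fill = "LV site") +
    ggplot2::theme_minimal()
}

#' Segment strain-time curves
#'
#' Mean maximum principal strain per LV wall segment versus time, with the
#' per-segment peak markers used by the dyssynchrony index.
#'
#' @param traces a `segment_traces` tibble from [segment_strain_traces()].
#' @return a ggplot object.
#' @export
plot_segment_traces <- function(traces) {
  peaks <- attr(traces, "peaks")
  p <- ggplot2::ggplot(traces, ggplot2::aes(x = .data$frame_ms, y = .data$e1,
                                            colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "segment-mean E1",
                  colour = "segment") +
    ggplot2::theme_minimal()
  if (!is.null(peaks))
    p <- p + ggplot2::geom_point(
      data = peaks, ggplot2::aes(x = .data$t_peak, y = .data$peak_e1,
                                 colour = .data$segment), size = 2)
  p
}

#' Histogram/map of nodal activation times
#'
#' @param map an `activation_map`.
#' @param mesh optional `heart_mesh`; when given, activation time is plotted
#'   against the short-axis angle coloured by z, showing the circumferential
#'   activation pattern.
#' @return a ggplot object.
#' @export
plot_activation_map <- function(map, mesh = NULL) {
  df <- tidy.activation_map(map)
  if (is.null(mesh)) {
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$t_act_ms)) +
             ggplot2::geom_histogram(bins = 40) +
             ggplot2::labs(x = "activation time (ms)", y = "nodes") +
             ggplot2::theme_minimal())
  }
  df$theta <- atan2(mesh$nodes[, 2], mesh$nodes[, 1])
  df$z <- mesh$nodes[, 3]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$t_act_ms,
                                   colour = .data$z)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "circumferential angle (rad)",
                  y = "activation time (ms)", colour = "z (mm)") +
    ggplot2::theme_minimal()
}
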