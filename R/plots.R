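#' @export
autoplot.dtw_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$d)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = .data$flagged), size = 2) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey55",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "adjacent-slice pair", y = "DTW warped-path value",
                  color = "flagged",
                  title = paste0("VB-DTW profile",
                                 if (!is.na(object$channel))
                                   paste0(" (", object$channel, ")") else ""),
                  subtitle = paste("threshold = mean D;",
                                   "valid slices:",
                                   paste(object$valid_slices,
                                         collapse = " "))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sensor_recording <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y") +
    ggplot2::labs(x = "sample", y = NULL,
                  title = paste("Recording", object$participant_id,
                                object$trial_id)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.motion_sequence <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y") +
    ggplot2::labs(x = "sample", y = NULL,
                  title = paste("Motion class", object$motion_class)) +
    ggplot2::theme_minimal()
}

#' Plot a family-by-channel-set accuracy table
#'
#' @param results tibble from [compare_families()].
#' @return a ggplot object.
#' @export
plot_family_comparison <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$channels, y = .data$family,
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data$accuracy)), color = "white") +
    ggplot2::scale_fill_gradient(low = "grey30", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "channel set", y = "model family",
                  title = "Segment-level accuracy by family and channels") +
    ggplot2::theme_minimal()
}
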