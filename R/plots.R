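#' Plot event-related averages
#'
#' One panel per stimulus duration; stimulus period shaded. If the era
#' carries a `compartment` or `layer` column, one line per group.
#'
#' @param era An `era` tibble (zeroed % signal change).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_era <- function(era, ...) {
  grp <- intersect(c("compartment", "layer"), names(era))
  p <- ggplot2::ggplot(era, ggplot2::aes(x = .data$time_s, y = .data$value))
  shade <- dplyr::distinct(era, .data$duration_s)
  p <- p + ggplot2::geom_rect(
    data = shade,
    ggplot2::aes(xmin = 0, xmax = .data$duration_s),
    ymin = -Inf, ymax = Inf, fill = "grey85", inherit.aes = FALSE)
  if (length(grp)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(colour = factor(.data[[grp[1]]])))
    p <- p + ggplot2::labs(colour = grp[1])
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~duration_s, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time from stimulus onset (s)",
                  y = "signal change (%)")
}

#' Plot a cortical depth profile
#'
#' @param profile A [layer_profile()] tibble (optionally with `duration_s`
#'   and `value_norm` columns from [minmax_normalise()]).
#' @param normalised Plot `value_norm` instead of `value` if present.
#' @return A ggplot object.
#' @export
plot_layer_profile <- function(profile, normalised = FALSE) {
  ycol <- if (normalised && "value_norm" %in% names(profile)) "value_norm"
  else "value"
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$layer, y = .data[[ycol]]))
  if ("duration_s" %in% names(profile))
    p <- p + ggplot2::geom_line(
      ggplot2::aes(colour = factor(.data$duration_s))) +
      ggplot2::labs(colour = "duration (s)")
  else p <- p + ggplot2::geom_line()
  p + ggplot2::labs(x = "layer (1 = deep)",
                    y = if (ycol == "value_norm") "normalised response"
                    else "response")
}

#' Plot a framewise-displacement trace
#'
#' @param fd FD tibble from [framewise_displacement()].
#' @param threshold_mm Threshold line; default 0.9 mm (the voxel size).
#' @return A ggplot object.
#' @export
plot_fd <- function(fd, threshold_mm = 0.9) {
  ggplot2::ggplot(fd, ggplot2::aes(x = .data$frame, y = .data$fd_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold_mm, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "volume", y = "framewise displacement (mm)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.era <- function(object, ...) plot_era(object, ...)
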