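#' Plots for bronchosum result objects
#'
#' @name plots
NULL

#' @describeIn plots Timeline of an edit decision list: selected shots as
#'   coloured bars over the source frame axis.
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bronch_edl <- function(object, ...) {
  df <- tidy(object)
  df$priority <- factor(df$priority, levels = PRIORITY_LEVELS)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = 0, ymax = 1, fill = .data$priority)) +
    ggplot2::xlim(0, attr(object, "frame_count")) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "source frame", y = NULL, fill = "priority",
                  title = "Summary edit decision list") +
    ggplot2::theme_minimal()
}

#' @describeIn plots Non-zero DCT fraction distributions of the benchmark
#'   classes with the trained decision threshold.
#' @export
autoplot.bronch_benchmark <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$fraction, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = object$fit$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "non-zero DCT coefficient fraction", y = "frames",
                  fill = NULL,
                  title = "DCT sparsity by frame class",
                  subtitle = sprintf("decision threshold %.4g",
                                     object$fit$threshold)) +
    ggplot2::theme_minimal()
}

#' Plot a luminance frame
#'
#' @param frame A luminance frame (matrix, 0--255).
#' @param main Plot title.
#' @return Invisibly, `frame`.
#' @export
plot_frame <- function(frame, main = "") {
  validate_frame(frame)
  graphics::image(t(frame)[, nrow(frame):1], col = grey.colors(256, 0, 1),
                  axes = FALSE, main = main, useRaster = TRUE)
  invisible(frame)
}
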