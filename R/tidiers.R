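#' Broom-style tidiers for bronchosum objects
#'
#' @param x The object to tidy.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.bronch_confusion <- function(x, ...) {
  tibble(cell = c("tp", "fp", "fn", "tn"),
         count = c(x$tp, x$fp, x$fn, x$tn))
}

#' @rdname tidiers
#' @export
tidy.bronch_dct_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$train_metrics, set = "train"),
    dplyr::mutate(x$test_metrics, set = "test"))
}

#' @rdname tidiers
#' @export
glance.bronch_dct_fit <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$test_metrics, names_from = "metric",
                             values_from = "value")
  dplyr::bind_cols(tibble(threshold = x$threshold, n = x$n,
                          n_train = length(x$split$train),
                          n_test = length(x$split$test)), wide)
}

#' @rdname tidiers
#' @export
tidy.bronch_benchmark <- function(x, ...) tidy(x$fit)

#' @rdname tidiers
#' @export
glance.bronch_benchmark <- function(x, ...) {
  dplyr::bind_cols(tibble(n_per_class = x$n_per_class, seed = x$seed),
                   glance(x$fit))
}

#' @rdname tidiers
#' @export
tidy.bronch_edl <- function(x, ...) {
  dplyr::mutate(as_tibble(x), length = .data$end - .data$start,
                seconds = .data$length / attr(x, "fps"))
}

#' @rdname tidiers
#' @export
glance.bronch_edl <- function(x, ...) {
  fps <- attr(x, "fps"); fc <- attr(x, "frame_count")
  len <- edl_length(x)
  tibble(n_shots = nrow(x), summary_frames = len,
         summary_seconds = len / fps, source_frames = fc,
         source_seconds = fc / fps,
         compression = if (len > 0) fc / len else NA_real_)
}

#' @export
print.bronch_edl <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<bronch_edl> %d shots, %d/%d frames (%.2f of %.2f s), compression %.3g\n",
    g$n_shots, g$summary_frames, g$source_frames, g$summary_seconds,
    g$source_seconds, g$compression))
  print(as_tibble(x))
  invisible(x)
}
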