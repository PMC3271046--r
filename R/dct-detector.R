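#' DCT-based non-informative frame detection
#'
#' Blurred, out-of-focus or smeared endoscopy frames carry almost no
#' high-frequency content: their 2-D DCT spectrum collapses onto the
#' low-order harmonics, so after zeroing small-magnitude coefficients very
#' few survive. Sharp mucosal texture keeps many coefficients above the
#' cutoff. The fraction of surviving coefficients therefore separates
#' informative from non-informative frames with a single trainable
#' decision threshold.
#'
#' @name dct-detector
NULL

# Orthonormal DCT-II basis matrix; cached per size.
dct_basis_cache <- new.env(parent = emptyenv())

dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(dct_basis_cache[[key]])) return(dct_basis_cache[[key]])
  k <- seq_len(n) - 1L
  m <- sqrt(2 / n) * cos(pi * outer(k, 2L * k + 1L) / (2L * n))
  m[1L, ] <- sqrt(1 / n)
  dct_basis_cache[[key]] <- m
  m
}

#' Orthonormal 2-D DCT-II of a matrix
#'
#' Computed as `C %*% x %*% t(C)` with the orthonormal DCT-II basis `C`,
#' so the transform preserves energy and the magnitude cutoff is
#' well-defined regardless of image size.
#'
#' @param x Numeric matrix.
#' @return Matrix of DCT coefficients, same dimensions as `x`.
#' @export
dct2 <- function(x) {
  dct_matrix(nrow(x)) %*% x %*% t(dct_matrix(ncol(x)))
}

#' Construct a DCT detector model
#'
#' @param magnitude_threshold Coefficient-magnitude cutoff below which DCT
#'   coefficients are zeroed. Default 20 (on the 0--255 luminance scale
#'   under the orthonormal transform); re-tunable for custom sensitivity.
#' @param decision_threshold Fraction of surviving coefficients at or above
#'   which a frame is called informative; in \[0, 1\]. Usually trained with
#'   [train_decision_threshold()].
#' @param working_size Square side length frames are resized to before the
#'   transform (default 256), removing the dependence of the raw non-zero
#'   count on camera resolution.
#' @return A `bronch_dct_model` object.
#' @export
dct_detector <- function(magnitude_threshold = 20, decision_threshold = 0.5,
                         working_size = 256L) {
  if (magnitude_threshold <= 0) abort("`magnitude_threshold` must be > 0")
  if (decision_threshold < 0 || decision_threshold > 1) {
    abort("`decision_threshold` must lie in [0, 1]")
  }
  if (working_size < 8L) abort("`working_size` must be at least 8")
  structure(
    list(magnitude_threshold = as.numeric(magnitude_threshold),
         decision_threshold = as.numeric(decision_threshold),
         working_size = as.integer(working_size)),
    class = "bronch_dct_model")
}

#' @export
print.bronch_dct_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<bronch_dct_model> |coef| cutoff %.6g, decision threshold %.6g, ",
    "working size %d\n"),
    x$magnitude_threshold, x$decision_threshold, x$working_size))
  invisible(x)
}

#' Fraction of DCT coefficients surviving the magnitude cutoff
#'
#' The frame is resized (bilinear) to `working_size x working_size`, the
#' orthonormal 2-D DCT-II is taken, coefficients with magnitude below
#' `magnitude_threshold` are set to zero, and the count of survivors is
#' divided by `working_size^2`.
#'
#' @param frame A luminance frame (numeric matrix, 0--255).
#' @param model A [dct_detector()] model.
#' @return A fraction in \[0, 1\].
#' @export
dct_nonzero_fraction <- function(frame, model = dct_detector()) {
  validate_frame(frame)
  ws <- model$working_size
  if (nrow(frame) != ws || ncol(frame) != ws) {
    frame <- resize_frame(frame, ws, ws)
  }
  coef <- dct2(frame)
  sum(abs(coef) >= model$magnitude_threshold) / (ws * ws)
}

# Bilinear resize, frame convention [row, col]; EBImage's first dimension
# is x, so dimensions are swapped symmetrically on the way in and out.
resize_frame <- function(frame, height, width) {
  t(EBImage::resize(t(frame), w = width, h = height, filter = "bilinear"))
}

#' Classify frames from their non-zero-fraction values
#'
#' A frame is informative iff its fraction is at or above the model's
#' decision threshold (ties classify as informative).
#'
#' @param fraction Numeric vector of fractions in \[0, 1\].
#' @param model A [dct_detector()] model.
#' @return Character vector in `c("informative", "non_informative")`.
#' @export
classify_fraction <- function(fraction, model) {
  stopifnot(all(fraction >= 0 & fraction <= 1))
  ifelse(fraction >= model$decision_threshold,
         "informative", "non_informative")
}

#' Classify every frame of a video
#'
#' @param video A [video_source()] or list of frames.
#' @param model A [dct_detector()] model.
#' @return A tibble with columns `frame` (0-based), `fraction`, `label`.
#' @export
classify_frames <- function(video, model = dct_detector()) {
  frames <- if (inherits(video, "video_source")) video$frames else video
  fr <- vapply(frames, dct_nonzero_fraction, numeric(1), model = model)
  tibble(frame = seq_along(frames) - 1L, fraction = fr,
         label = classify_fraction(fr, model))
}

f_measure_at <- function(threshold, fraction, truth) {
  # positive class = non_informative; predicted positive iff fraction < t
  pred_pos <- fraction < threshold
  true_pos <- truth == "non_informative"
  tp <- sum(pred_pos & true_pos)
  fp <- sum(pred_pos & !true_pos)
  fn <- sum(!pred_pos & true_pos)
  if (tp == 0L) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Train the decision threshold of the DCT detector
#'
#' The labelled fractions are split evenly (but randomly) into a training
#' and a testing half. Candidate thresholds are 0, 1, and the midpoints
#' between consecutive distinct sorted training fractions; the candidate
#' maximizing F-measure on the training half (non-informative as the
#' positive class) is selected, ties broken toward the larger threshold.
#'
#' @param fraction Numeric vector of non-zero DCT fractions.
#' @param label Character vector in
#'   `c("informative", "non_informative")`, one per fraction.
#' @param split_seed Seed for the even random split, or `NULL` to train
#'   (and report metrics) on the full labelled set without holding out a
#'   test half.
#' @param magnitude_threshold,working_size Passed through to the returned
#'   model (the fractions must have been computed under the same settings).
#' @return A list of class `bronch_dct_fit`: `model` (the trained
#'   [dct_detector()]), `threshold`, `train_metrics` / `test_metrics`
#'   tibbles, and the `split` index list.
#' @export
train_decision_threshold <- function(fraction, label, split_seed = 1L,
                                     magnitude_threshold = 20,
                                     working_size = 256L) {
  stopifnot(length(fraction) == length(label))
  if (!all(label %in% c("informative", "non_informative"))) {
    abort("labels must be 'informative' or 'non_informative'")
  }
  if (length(unique(label)) < 2L || min(table(label)) < 2L) {
    abort("training needs at least 2 examples of each class")
  }
  split <- if (is.null(split_seed)) {
    list(train = seq_along(fraction), test = seq_along(fraction))
  } else {
    split_even_random(length(fraction), seed = split_seed)
  }
  tr_f <- fraction[split$train]; tr_l <- label[split$train]
  te_f <- fraction[split$test];  te_l <- label[split$test]

  s <- sort(unique(tr_f))
  candidates <- c(0, if (length(s) > 1L) (head(s, -1L) + tail(s, -1L)) / 2, 1)
  f1 <- vapply(candidates, f_measure_at, numeric(1),
               fraction = tr_f, truth = tr_l)
  best <- max(f1)
  threshold <- max(candidates[f1 >= best - 1e-12])  # ties -> larger

  model <- dct_detector(magnitude_threshold, threshold, working_size)
  eval_half <- function(f, l) {
    cm <- confusion(classify_fraction(f, model), l)
    classification_metrics(cm)
  }
  structure(
    list(model = model, threshold = threshold,
         train_metrics = eval_half(tr_f, tr_l),
         test_metrics = eval_half(te_f, te_l),
         split = split, n = length(fraction)),
    class = "bronch_dct_fit")
}

#' @export
print.bronch_dct_fit <- function(x, ...) {
  cat(sprintf("<bronch_dct_fit> threshold %.6g (n = %d; %d train / %d test)\n",
              x$threshold, x$n, length(x$split$train), length(x$split$test)))
  cat("test-half metrics:\n")
  print(x$test_metrics)
  invisible(x)
}

#' Save / load a DCT detector model as JSON
#'
#' Schema: `{"magnitude_threshold": number, "decision_threshold": number,
#' "working_size": int}`.
#'
#' @param model A [dct_detector()] model.
#' @param path JSON file path.
#' @return `path` invisibly / the loaded model.
#' @export
save_dct_model <- function(model, path) {
  stopifnot(inherits(model, "bronch_dct_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dct_model
#' @export
load_dct_model <- function(path) {
  raw <- jsonlite::fromJSON(path)
  dct_detector(raw$magnitude_threshold, raw$decision_threshold,
               raw$working_size)
}
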