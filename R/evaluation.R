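#' Classifier evaluation: confusion counts, metrics, benchmark
#'
#' The detection task is framed with the *non-informative* class as
#' positive. Note on naming: some clinical evaluation tables print the
#' quantity `tp / (tp + fp)` — precision — under the heading
#' "specificity". Both precision and the standard specificity
#' `tn / (tn + fp)` are therefore reported, explicitly labelled.
#'
#' @name evaluation
NULL

#' Confusion matrix for two-class frame labels
#'
#' @param predicted,truth Character vectors of equal length with values in
#'   `c("informative", "non_informative")`.
#' @param positive The positive class (default `"non_informative"`: the
#'   detection target).
#' @return A `bronch_confusion` object with counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(predicted, truth, positive = "non_informative") {
  if (length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must have equal length")
  }
  lv <- c("informative", "non_informative")
  if (!all(predicted %in% lv) || !all(truth %in% lv)) {
    abort("labels must be 'informative' or 'non_informative'")
  }
  pp <- predicted == positive; tp_ <- truth == positive
  structure(list(tp = sum(pp & tp_), fp = sum(pp & !tp_),
                 fn = sum(!pp & tp_), tn = sum(!pp & !tp_),
                 positive = positive),
            class = "bronch_confusion")
}

#' @export
print.bronch_confusion <- function(x, ...) {
  cat(sprintf("<bronch_confusion> positive = %s\n", x$positive))
  cat(sprintf("  tp %d  fp %d\n  fn %d  tn %d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

safe_ratio <- function(num, den, name) {
  if (den == 0) {
    warn(sprintf("%s is undefined (zero denominator)", name))
    return(NA_real_)
  }
  num / den
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, precision `tp/(tp+fp)` (the quantity some
#' clinical tables print as "specificity"), standard specificity
#' `tn/(tn+fp)`, accuracy `(tp+tn)/n`, and F-measure `2PR/(P+R)`.
#' Metrics with a zero denominator are reported as `NA` with a warning
#' rather than coerced to 0.
#'
#' @param cm A [confusion()] object.
#' @return A tibble with columns `metric`, `value`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "bronch_confusion"))
  sens <- safe_ratio(cm$tp, cm$tp + cm$fn, "sensitivity")
  prec <- safe_ratio(cm$tp, cm$tp + cm$fp, "precision")
  spec <- safe_ratio(cm$tn, cm$tn + cm$fp, "specificity")
  acc <- safe_ratio(cm$tp + cm$tn, cm$tp + cm$fp + cm$fn + cm$tn, "accuracy")
  f1 <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0) {
    warn("f_measure is undefined")
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  tibble(metric = c("sensitivity", "precision", "specificity", "accuracy",
                    "f_measure"),
         value = c(sens, prec, spec, acc, f1))
}

#' Even random split into training and testing halves
#'
#' A uniformly random permutation under `seed`; the first half (with the
#' extra item when the count is odd) is the training set. The two halves
#' are disjoint and exhaustive.
#'
#' @param n Number of items (or a vector whose length is used).
#' @param seed Integer seed.
#' @return A list with integer index vectors `train` and `test`.
#' @export
split_even_random <- function(n, seed = 1L) {
  if (length(n) > 1L) n <- length(n)
  if (n < 2L) abort("need at least 2 items to split")
  perm <- withr::with_seed(seed, sample.int(n))
  k <- ceiling(n / 2)
  list(train = perm[seq_len(k)], test = perm[(k + 1L):n])
}

#' Run the synthetic frame-classification benchmark
#'
#' Generates `n_per_class` sharp and `n_per_class` blurred synthetic
#' frames, computes their non-zero DCT fractions, splits them evenly at
#' random, trains the decision threshold on the training half (maximizing
#' F-measure with non-informative as positive), and reports the metrics on
#' the held-out half.
#'
#' @param n_per_class Frames per class (>= 10).
#' @param seed Seed for frame generation and the split.
#' @param size Frame side in pixels.
#' @param sigma_range Blur sigma range for the non-informative class.
#' @param magnitude_threshold,working_size DCT detector settings.
#' @return A `bronch_benchmark` object: `fit` (the
#'   [train_decision_threshold()] result), `data` (per-frame tibble with
#'   `label`, `sigma`, `fraction`), `n_per_class`, `seed`.
#' @export
run_benchmark <- function(n_per_class = 200L, seed = 42L, size = 256L,
                          sigma_range = c(6, 12), magnitude_threshold = 20,
                          working_size = 256L) {
  if (n_per_class < 10L) abort("`n_per_class` must be at least 10")
  set <- make_benchmark_set(n_per_class, seed, size, sigma_range)
  probe <- dct_detector(magnitude_threshold, 0.5, working_size)
  fr <- vapply(set$frames, dct_nonzero_fraction, numeric(1), model = probe)
  fit <- train_decision_threshold(fr, set$label, split_seed = seed,
                                  magnitude_threshold = magnitude_threshold,
                                  working_size = working_size)
  structure(
    list(fit = fit,
         data = tibble(id = seq_along(fr) - 1L, label = set$label,
                       sigma = set$sigma, fraction = fr),
         n_per_class = as.integer(n_per_class), seed = as.integer(seed)),
    class = "bronch_benchmark")
}

#' @export
print.bronch_benchmark <- function(x, ...) {
  cat(sprintf("<bronch_benchmark> %d frames/class, seed %d, threshold %.4g\n",
              x$n_per_class, x$seed, x$fit$threshold))
  cat("held-out test metrics:\n")
  print(x$fit$test_metrics)
  invisible(x)
}
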