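# Independent oracles used across the suite.

# Naive orthonormal 2-D DCT-II: each coefficient evaluated from its
# defining double sum (no basis-matrix products).
naive_dct2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  ci <- (2 * (0:(n - 1)) + 1) * pi / (2 * n)
  cj <- (2 * (0:(m - 1)) + 1) * pi / (2 * m)
  for (u in 0:(n - 1)) {
    au <- if (u == 0) sqrt(1 / n) else sqrt(2 / n)
    for (v in 0:(m - 1)) {
      av <- if (v == 0) sqrt(1 / m) else sqrt(2 / m)
      out[u + 1, v + 1] <- au * av * sum(x * outer(cos(ci * u), cos(cj * v)))
    }
  }
  out
}

# Non-zero count after the magnitude cutoff, from the naive transform.
naive_nonzero_count <- function(x, cutoff = 20) {
  sum(abs(naive_dct2(x)) >= cutoff)
}

# Exhaustive F-measure threshold sweep (positive = non_informative,
# predicted positive iff fraction < t).
sweep_f_measure <- function(t, fraction, label) {
  pred <- ifelse(fraction < t, "non_informative", "informative")
  tp <- sum(pred == "non_informative" & label == "non_informative")
  fp <- sum(pred == "non_informative" & label == "informative")
  fn <- sum(pred == "informative" & label == "non_informative")
  if (tp == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

# Count pixels at or below the dark cutoff (the pre-morphology mask).
dark_pixel_count <- function(frame, dark_threshold = 40) {
  sum(frame <= dark_threshold)
}

# Random label track for summarizer property tests.
random_track <- function(seed, n = 400) {
  withr::with_seed(seed, {
    informative <- runif(n) > 0.2
    branching <- informative & runif(n) < 0.1
    tag <- function(p) informative & runif(n) < p
    frame_label_track(informative, branching, marker = tag(0.02),
                      annotation = tag(0.02), lesion = tag(0.03))
  })
}

# Plain shot tibble from an EDL (drops the fps/frame_count attributes).
shot_tbl <- function(edl) {
  tibble::tibble(start = edl$start, end = edl$end, priority = edl$priority)
}

# Shared EDL invariant assertions.
expect_edl_valid <- function(edl, track, budget,
                             config = summary_config()) {
  # sorted, pairwise disjoint, in bounds
  if (nrow(edl) > 1) {
    expect_true(all(edl$start[-1] >= edl$end[-nrow(edl)]))
  }
  expect_true(all(edl$start < edl$end))
  expect_true(all(edl$start >= 0 & edl$end <= nrow(track)))
  # budget compliance
  len <- edl_length(edl)
  expect_lte(len, budget)
  shots <- build_shots(track, config)
  material <- sum(shots$end - shots$start)
  if (material >= budget) expect_gte(len, budget - 1)
  # exclusion of non-informative frames
  sel <- unlist(mapply(function(a, b) seq.int(a, b - 1), edl$start, edl$end,
                       SIMPLIFY = FALSE))
  expect_true(all(track$informative[sel + 1]))
}
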