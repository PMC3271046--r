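#' Synthetic endoscopy-like frames and scripted videos
#'
#' Clinical bronchoscopy recordings cannot ship with a package, so the
#' generator emulates the image properties the detectors rely on: a bright
#' vignetted wall texture rich in mid/high spatial frequencies (mucosa),
#' one to three large near-black lumen disks (airway openings), and
#' Gaussian-blurred counterparts standing in for non-informative frames.
#' Everything is deterministic under a seed.
#'
#' @name synthetic
NULL

SEGMENT_KINDS <- c("sharp_single_lumen", "sharp_bifurcation", "blurred",
                   "lesion_tagged")

# Symmetric (reflected) padding by p pixels on every side.
reflect_pad <- function(x, p) {
  n <- nrow(x); m <- ncol(x)
  ri <- c(seq(p, 1L), seq_len(n), seq(n, n - p + 1L))
  ci <- c(seq(p, 1L), seq_len(m), seq(m, m - p + 1L))
  x[ri, ci]
}

# Gaussian blur on an arbitrary numeric matrix, reflected boundary.
blur_raw <- function(x, sigma) {
  p <- min(as.integer(ceiling(3 * sigma)), min(dim(x)) - 1L)
  padded <- EBImage::gblur(reflect_pad(x, p), sigma = sigma,
                           radius = 2L * p + 1L)
  padded[(p + 1L):(p + nrow(x)), (p + 1L):(p + ncol(x))]
}

#' Gaussian-blur a frame (non-informative counterpart)
#'
#' Applies a Gaussian blur with reflected boundary handling and clips back
#' to the 0--255 range. With `sigma` in the 6--12 range this emulates the
#' gross defocus/motion blur of non-informative frames.
#'
#' @param base A luminance frame.
#' @param sigma Blur standard deviation in pixels (>= 2).
#' @return The blurred frame.
#' @export
make_noninformative_frame <- function(base, sigma) {
  validate_frame(base)
  if (sigma < 2) abort("`sigma` must be at least 2 for a non-informative frame")
  pmin(pmax(blur_raw(base, sigma), 0), 255)
}

lumen_centers <- function(size, r, n_lumina) {
  c0 <- (size + 1) / 2
  theta <- runif(1, 0, 2 * pi)
  if (n_lumina == 1L) {
    jit <- runif(2, -0.1, 0.1) * size
    return(cbind(c0 + jit[1], c0 + jit[2]))
  }
  d <- if (n_lumina == 2L) 1.6 * r else 1.8 * r
  ang <- theta + 2 * pi * (seq_len(n_lumina) - 1L) / n_lumina
  cbind(c0 + d * sin(ang), c0 + d * cos(ang))
}

#' Generate a sharp (informative) endoscopy-like frame
#'
#' A bright band-limited wall texture (high-pass filtered noise plus a
#' low-frequency illumination component), attenuated by a radial vignette,
#' with `n_lumina` non-overlapping near-black lumen disks. The disk
#' geometry guarantees the branch detector's separability margins: disk
#' radius is at least `0.1 * size`, disk interiors stay at or below
#' luminance 20, edge-to-edge separation is at least one radius, and the
#' wall never drops below luminance 75.
#'
#' @param seed Integer seed; the same seed reproduces the frame exactly.
#' @param size Square frame side in pixels (>= 64).
#' @param n_lumina Number of lumen disks: 1 (single airway view), 2 or 3
#'   (bifurcation views).
#' @return A list with `frame` (the luminance matrix) and `lumina`
#'   (ground-truth tibble: `row`, `col` 0-based centers, `radius`).
#' @export
make_informative_frame <- function(seed, size = 256L, n_lumina = 1L) {
  if (size < 64L) abort("`size` must be at least 64")
  if (!n_lumina %in% 1:3) abort("`n_lumina` must be 1, 2 or 3")
  withr::with_seed(seed, {
    noise <- matrix(rnorm(size * size), size, size)
    hp <- noise - blur_raw(noise, 3)
    lowf <- blur_raw(matrix(rnorm(size * size), size, size), size / 16)
    tex <- hp / stats::sd(hp) * 35 + lowf / stats::sd(lowf) * 15
    cc <- (seq_len(size) - (size + 1) / 2) / (size / 2)
    d2 <- outer(cc^2, cc^2, `+`)
    vig <- 1 - 0.25 * pmin(d2 / 2, 1)
    wall <- pmin(pmax((165 + tex) * vig, 75), 255)

    r <- runif(1, 0.10, 0.13) * size
    centers <- lumen_centers(size, r, n_lumina)
    u <- matrix(runif(size * size), size, size)
    frame <- wall
    rows <- matrix(seq_len(size), size, size)
    cols <- t(rows)
    for (k in seq_len(n_lumina)) {
      inside <- (rows - centers[k, 1L])^2 + (cols - centers[k, 2L])^2 <= r^2
      frame[inside] <- 6 + 8 * u[inside]
    }
    list(frame = frame,
         lumina = tibble(row = centers[, 1L] - 1, col = centers[, 2L] - 1,
                         radius = r))
  })
}

#' Define a scene script for a synthetic video
#'
#' @param kind Character vector of segment kinds, each one of
#'   `"sharp_single_lumen"`, `"sharp_bifurcation"`, `"blurred"`,
#'   `"lesion_tagged"`.
#' @param duration Integer vector of segment durations in frames (>= 1).
#' @param fps Frame rate of the scripted video.
#' @param seed Seed fixing all randomness of the rendered video.
#' @return A `bronch_script` tibble with columns `kind`, `duration`.
#' @export
scene_script <- function(kind, duration, fps = 25, seed = 1L) {
  if (!all(kind %in% SEGMENT_KINDS)) {
    abort(sprintf("segment kinds must be among: %s",
                  paste(SEGMENT_KINDS, collapse = ", ")))
  }
  if (any(duration < 1L)) abort("segment durations must be >= 1 frame")
  structure(tibble(kind = kind, duration = as.integer(duration)),
            fps = fps, seed = as.integer(seed),
            class = c("bronch_script", class(tibble())))
}

frame_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483562)
}

#' Render a scene script into a video with ground truth
#'
#' Segments are rendered frame by frame (each frame gets a fresh seeded
#' texture, emulating scope motion). Blurred segments are non-informative
#' ground truth (a per-segment sigma is drawn uniformly from
#' `sigma_range`); bifurcation segments are branching ground truth;
#' `lesion_tagged` segments carry one lesion annotation at their central
#' frame.
#'
#' @param script A [scene_script()].
#' @param size Frame side in pixels.
#' @param sigma_range Range of blur sigmas for `blurred` segments.
#' @return A list: `video` ([video_source()]), `track` (ground-truth
#'   [frame_label_track()]), `annotations` ([annotation_set()]).
#' @export
make_video <- function(script, size = 128L, sigma_range = c(6, 12)) {
  stopifnot(inherits(script, "bronch_script"))
  fps <- attr(script, "fps"); seed <- attr(script, "seed")
  n <- sum(script$duration)
  frames <- vector("list", n)
  informative <- branching <- lesion <- rep(FALSE, n)
  ann_frame <- integer(); ann_label <- character()
  gidx <- 0L
  for (s in seq_len(nrow(script))) {
    kind <- script$kind[s]; dur <- script$duration[s]
    sigma <- withr::with_seed(frame_seed(seed, 100000L + s),
                              runif(1, sigma_range[1L], sigma_range[2L]))
    for (j in seq_len(dur)) {
      gidx <- gidx + 1L
      fs <- frame_seed(seed, gidx)
      if (kind == "sharp_bifurcation") {
        frames[[gidx]] <- make_informative_frame(fs, size, 2L)$frame
        informative[gidx] <- TRUE; branching[gidx] <- TRUE
      } else if (kind == "blurred") {
        base <- make_informative_frame(fs, size, 1L)$frame
        frames[[gidx]] <- make_noninformative_frame(base, sigma)
      } else {
        frames[[gidx]] <- make_informative_frame(fs, size, 1L)$frame
        informative[gidx] <- TRUE
      }
    }
    if (kind == "lesion_tagged") {
      center <- gidx - dur + 1L + dur %/% 2L
      lesion[center] <- TRUE
      ann_frame <- c(ann_frame, center - 1L)
      ann_label <- c(ann_label, sprintf("lesion-seg%d", s))
    }
  }
  ann <- annotation_set(frame = ann_frame,
                        class = rep("lesion", length(ann_frame)),
                        label = ann_label, fps = fps, frame_count = n)
  list(video = video_source(frames, fps = fps),
       track = frame_label_track(informative, branching,
                                 lesion = lesion),
       annotations = ann)
}

#' Generate the sharp/blurred benchmark frame set
#'
#' `n_per_class` sharp frames (lumen count drawn from 1--3) and their
#' Gaussian-blurred counterparts with per-frame sigma drawn uniformly from
#' `sigma_range`.
#'
#' @param n_per_class Frames per class.
#' @param seed Seed fixing frames and sigmas.
#' @param size Frame side in pixels.
#' @param sigma_range Blur sigma range for the non-informative class.
#' @return A list: `frames` (list of matrices, sharp first), `label`
#'   (character vector), `sigma` (NA for sharp frames).
#' @export
make_benchmark_set <- function(n_per_class, seed = 42L, size = 256L,
                               sigma_range = c(6, 12)) {
  n_lumina <- withr::with_seed(frame_seed(seed, 500000L),
                               sample(1:3, n_per_class, replace = TRUE))
  sigmas <- withr::with_seed(frame_seed(seed, 600000L),
                             runif(n_per_class, sigma_range[1L],
                                   sigma_range[2L]))
  sharp <- lapply(seq_len(n_per_class), function(i) {
    make_informative_frame(frame_seed(seed, i), size, n_lumina[i])$frame
  })
  blurred <- lapply(seq_len(n_per_class), function(i) {
    make_noninformative_frame(sharp[[i]], sigmas[i])
  })
  list(frames = c(sharp, blurred),
       label = rep(c("informative", "non_informative"), each = n_per_class),
       sigma = c(rep(NA_real_, n_per_class), sigmas))
}
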