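#' Airway-bifurcation detection from dark lumen regions
#'
#' Down the axis of the bronchoscope the airway lumen appears as a large,
#' dark (non-illuminated) region. At a branching point two or more daughter
#' lumina are visible at once, so counting sufficiently large dark regions
#' identifies frames showing bifurcations.
#'
#' @name branch-detector
NULL

#' Branch detector parameters
#'
#' @param dark_threshold Luminance cutoff (0--255, exclusive bounds) below
#'   or at which a pixel counts as dark. Default 40: lumen interiors are
#'   near-black under endoscopic illumination.
#' @param se_radius Disc radius (pixels) of the structuring element used
#'   for the morphological opening and closing. Default 5.
#' @param min_area_fraction Minimum region area as a fraction of the frame
#'   pixel count; encodes "relatively large". Default 0.01.
#' @return A `bronch_branch_params` object.
#' @export
branch_params <- function(dark_threshold = 40, se_radius = 5,
                          min_area_fraction = 0.01) {
  if (dark_threshold <= 0 || dark_threshold >= 255) {
    abort("`dark_threshold` must lie strictly between 0 and 255")
  }
  if (se_radius < 1) abort("`se_radius` must be at least 1")
  if (min_area_fraction <= 0 || min_area_fraction >= 1) {
    abort("`min_area_fraction` must lie strictly between 0 and 1")
  }
  structure(list(dark_threshold = dark_threshold,
                 se_radius = as.integer(se_radius),
                 min_area_fraction = min_area_fraction),
            class = "bronch_branch_params")
}

# Merge 4-connected labels that touch diagonally, yielding 8-connected
# components (EBImage::bwlabel is 4-connected).
label_8connected <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), if (off[2L] > 0) seq_len(nc - 1L) else 2L:nc]
    b <- lab[2L:nr, if (off[2L] > 0) 2L:nc else seq_len(nc - 1L)]
    touch <- a > 0 & b > 0 & a != b
    if (any(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment large dark regions of a frame
#'
#' The luminance is complemented and thresholded (a pixel is dark iff its
#' complement is at or above `255 - dark_threshold`), the binary mask is
#' cleaned by a morphological opening followed by a closing with a disc of
#' `se_radius`, 8-connected components are labelled, and regions with area
#' at or above `min_area_fraction` of the frame pixels are returned,
#' largest first.
#'
#' @param frame A luminance frame (numeric matrix, 0--255).
#' @param params A [branch_params()] object.
#' @return A tibble with one row per retained dark region: `label_id`,
#'   `area` (pixels), `centroid_row`, `centroid_col`, and the half-open
#'   0-based bounding box `top`, `left`, `bottom`, `right`; sorted by
#'   decreasing area.
#' @export
segment_dark_regions <- function(frame, params = branch_params()) {
  validate_frame(frame)
  mask <- (255 - frame) >= (255 - params$dark_threshold)
  mask <- matrix(as.numeric(mask), nrow(frame), ncol(frame))
  brush <- EBImage::makeBrush(2L * params$se_radius + 1L, shape = "disc")
  mask <- EBImage::closing(EBImage::opening(mask, brush), brush)
  lab <- label_8connected(mask)
  empty <- tibble(label_id = integer(), area = integer(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  top = integer(), left = integer(),
                  bottom = integer(), right = integer())
  nlab <- max(lab)
  if (nlab == 0L) return(empty)
  idx <- which(lab > 0)
  l <- lab[idx]
  nr <- nrow(lab)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  out <- tibble(
    label_id = seq_len(nlab),
    area = as.integer(tabulate(l, nlab)),
    centroid_row = as.numeric(rowsum(rows, l)) / tabulate(l, nlab) - 1,
    centroid_col = as.numeric(rowsum(cols, l)) / tabulate(l, nlab) - 1,
    top = as.integer(tapply(rows, l, min)) - 1L,
    left = as.integer(tapply(cols, l, min)) - 1L,
    bottom = as.integer(tapply(rows, l, max)),
    right = as.integer(tapply(cols, l, max)))
  min_area <- params$min_area_fraction * nrow(frame) * ncol(frame)
  out <- dplyr::arrange(dplyr::filter(out, .data$area >= min_area),
                        dplyr::desc(.data$area))
  out
}

#' Is a frame showing a branching point?
#'
#' Two or more large dark lumen regions in one view identify a frame
#' showing a branching point of the airway tree.
#'
#' @param regions Output of [segment_dark_regions()].
#' @return `TRUE` iff at least two regions are present.
#' @export
is_branching <- function(regions) {
  nrow(regions) >= 2L
}

#' Detect branching frames across a video
#'
#' @param video A [video_source()] or list of frames.
#' @param params A [branch_params()] object.
#' @return A tibble with columns `frame` (0-based), `n_regions`,
#'   `is_branching`.
#' @export
detect_branching <- function(video, params = branch_params()) {
  frames <- if (inherits(video, "video_source")) video$frames else video
  res <- purrr::map(frames, segment_dark_regions, params = params)
  tibble(frame = seq_along(frames) - 1L,
         n_regions = vapply(res, nrow, integer(1)),
         is_branching = vapply(res, is_branching, logical(1)))
}
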