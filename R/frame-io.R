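#' Frames, videos and annotation files
#'
#' A *frame* is a plain numeric matrix of luminance values on the 0--255
#' scale, with rows running down the image (`frame[row, col]`). A *video*
#' is an ordered sequence of equally sized frames plus a frame rate.
#' Annotation sets and edit decision lists are tibble-backed objects with
#' lossless JSON round-trips.
#'
#' @name frame-io
NULL

TAG_CLASSES <- c("marker", "annotation", "lesion")

#' Validate a luminance frame
#'
#' Checks the frame invariants: a numeric matrix of at least 8x8 pixels
#' with all values in \[0, 255\].
#'
#' @param frame Numeric matrix of luminance values (0--255).
#' @return The frame, invisibly. Errors on violation.
#' @export
validate_frame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    abort("`frame` must be a numeric matrix of luminance values.")
  }
  if (nrow(frame) < 8L || ncol(frame) < 8L) {
    abort(sprintf("frames must be at least 8x8 pixels, got %dx%d",
                  nrow(frame), ncol(frame)))
  }
  if (anyNA(frame) || min(frame) < 0 || max(frame) > 255) {
    abort("frame values must lie within [0, 255] and contain no NA")
  }
  invisible(frame)
}

#' Convert an RGB frame to luminance
#'
#' Collapses a 3-channel colour frame to a single luminance channel using
#' the ITU-R BT.601 luma weights (0.299 R + 0.587 G + 0.114 B), i.e. the
#' hue and saturation are discarded and only the luminance is retained.
#'
#' @param rgb A `height x width x 3` numeric array with values in \[0, 255\].
#' @return A luminance frame (numeric matrix, 0--255).
#' @examples
#' rgb <- array(255, dim = c(16, 16, 3))
#' range(to_luminance(rgb))  # constant 255
#' @export
to_luminance <- function(rgb) {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L) {
    abort("`rgb` must be a height x width x 3 array")
  }
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255) {
    abort("RGB values must lie within [0, 255]")
  }
  y <- 0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
  pmin(pmax(y, 0), 255)
}

#' Construct a video from frames in memory
#'
#' @param frames List of luminance frames (numeric matrices 0--255), all of
#'   identical dimensions.
#' @param fps Frame rate in frames/second (> 0).
#' @return A `video_source` object with fields `frames`, `fps`,
#'   `frame_count`, `height`, `width`.
#' @export
video_source <- function(frames, fps = 25) {
  if (length(frames) < 1L) abort("a video needs at least one frame")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    abort("`fps` must be a single positive number")
  }
  validate_frame(frames[[1L]])
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    validate_frame(f)
    if (nrow(f) != h || ncol(f) != w) {
      abort(sprintf(
        "frame %d has dimensions %dx%d, expected the constant %dx%d",
        i - 1L, nrow(f), ncol(f), h, w))
    }
  }
  structure(
    list(frames = frames, fps = fps, frame_count = length(frames),
         height = h, width = w),
    class = "video_source")
}

#' @export
print.video_source <- function(x, ...) {
  cat(sprintf("<video_source> %d frames, %dx%d px, %.6g fps (%.2f s)\n",
              x$frame_count, x$height, x$width, x$fps,
              x$frame_count / x$fps))
  invisible(x)
}

#' Access one frame of a video by 0-based index
#'
#' @param video A [video_source()].
#' @param index 0-based frame index in `[0, frame_count)`.
#' @return A luminance frame.
#' @export
video_frame <- function(video, index) {
  stopifnot(inherits(video, "video_source"))
  if (index < 0 || index >= video$frame_count) {
    abort(sprintf("frame index %d out of range [0, %d)",
                  index, video$frame_count))
  }
  video$frames[[index + 1L]]
}

#' Duration of a video in seconds
#' @param video A [video_source()].
#' @return `frame_count / fps`.
#' @export
video_duration <- function(video) video$frame_count / video$fps

read_one_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    px <- px[, , seq_len(min(dim(px)[3L], 3L)), drop = FALSE]
    if (dim(px)[3L] == 3L) return(to_luminance(px * 255))
    px <- px[, , 1L]
  }
  px * 255
}

#' Read a video from an image-sequence directory
#'
#' Frames are PNG files read in lexicographic filename order (the writer
#' uses `frame_%06d.png`). Container-file decoding is not available in this
#' build; decode to an image sequence first.
#'
#' @param path Directory containing PNG frames.
#' @param fps Frame rate to assume for the sequence (image files carry no
#'   timing metadata). Defaults to 25 frames/second.
#' @return A [video_source()].
#' @export
read_video <- function(path, fps = 25) {
  if (!dir.exists(path)) abort(sprintf("video source not readable: %s", path))
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) {
    abort(sprintf("no decodable frames found in %s", path))
  }
  video_source(lapply(files, read_one_image), fps = fps)
}

#' Write frames as a PNG image sequence
#'
#' @param frames List of luminance frames.
#' @param dir Output directory (created if missing).
#' @param start_index First index used in `frame_%06d.png` names.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, dir, start_index = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    paths[i] <- file.path(dir, sprintf("frame_%06d.png", start_index + i - 1L))
    png::writePNG(pmin(pmax(frames[[i]], 0), 255) / 255, paths[i])
  }
  invisible(paths)
}

#' Construct an annotation set
#'
#' Physician-facing frame tags: manually introduced treatment `marker`s,
#' free-text physician `annotation`s, and automatically detected `lesion`
#' tags. Stored as a tibble with columns `frame` (0-based), `class`, `label`.
#'
#' @param frame Integer vector of 0-based frame indices.
#' @param class Character vector from `c("marker", "annotation", "lesion")`.
#' @param label Character vector of free-text labels.
#' @param fps Frame rate the indices refer to.
#' @param frame_count Optional frame count for bounds checking.
#' @return A `bronch_annotations` tibble.
#' @export
annotation_set <- function(frame = integer(), class = character(),
                           label = character(), fps = 25,
                           frame_count = NULL) {
  entries <- tibble(frame = as.integer(frame), class = as.character(class),
                    label = as.character(label))
  for (i in seq_len(nrow(entries))) {
    if (!entries$class[i] %in% TAG_CLASSES) {
      abort(sprintf("entry %d: unknown tag class '%s'", i, entries$class[i]))
    }
    if (is.na(entries$frame[i]) || entries$frame[i] < 0L) {
      abort(sprintf("entry %d: frame index %s out of range",
                    i, entries$frame[i]))
    }
    if (!is.null(frame_count) && entries$frame[i] >= frame_count) {
      abort(sprintf("entry %d: frame index %d beyond frame count %d",
                    i, entries$frame[i], frame_count))
    }
  }
  structure(entries, fps = fps,
            class = c("bronch_annotations", class(entries)))
}

#' Load annotations from JSON
#'
#' Schema: `{"fps": number, "entries": [{"frame": int, "class":
#' "marker|annotation|lesion", "label": str}, ...]}`.
#'
#' @param path JSON file path.
#' @param frame_count Optional bound on frame indices.
#' @return A `bronch_annotations` tibble.
#' @export
load_annotations <- function(path, frame_count = NULL) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  entries <- raw$entries
  if (is.null(entries) || length(entries) == 0L) {
    return(annotation_set(fps = raw$fps %||% 25, frame_count = frame_count))
  }
  annotation_set(entries$frame, entries$class, entries$label,
                 fps = raw$fps %||% 25, frame_count = frame_count)
}

#' Save annotations to JSON
#' @param ann A `bronch_annotations` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "bronch_annotations"))
  entries <- lapply(seq_len(nrow(ann)), function(i) {
    list(frame = ann$frame[i], class = ann$class[i], label = ann$label[i])
  })
  jsonlite::write_json(list(fps = attr(ann, "fps"), entries = entries),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Save an edit decision list
#'
#' JSON schema: `{"fps": number, "frame_count": int, "shots": [{"start":
#' int, "end": int, "priority": str}, ...]}`. A `.csv` path writes the same
#' columns as CSV (fps and frame count go into a header comment-free first
#' row via attributes being dropped; prefer JSON for lossless round-trips).
#'
#' @param edl A [edit_decision_list()].
#' @param path Output path ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
save_edl <- function(edl, path) {
  stopifnot(inherits(edl, "bronch_edl"))
  if (grepl("\\.csv$", path)) {
    write.csv(as_tibble(edl), path, row.names = FALSE)
    return(invisible(path))
  }
  shots <- lapply(seq_len(nrow(edl)), function(i) {
    list(start = edl$start[i], end = edl$end[i], priority = edl$priority[i])
  })
  jsonlite::write_json(
    list(fps = attr(edl, "fps"), frame_count = attr(edl, "frame_count"),
         shots = shots),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load an edit decision list from JSON
#' @param path JSON file written by [save_edl()].
#' @return A `bronch_edl` object.
#' @export
load_edl <- function(path) {
  if (!file.exists(path)) abort(sprintf("EDL file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  shots <- raw$shots
  if (is.null(shots) || length(shots) == 0L) {
    shots <- tibble(start = integer(), end = integer(), priority = character())
  }
  edit_decision_list(tibble(start = as.integer(shots$start),
                            end = as.integer(shots$end),
                            priority = as.character(shots$priority)),
                     fps = raw$fps, frame_count = raw$frame_count)
}
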