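#' Summary assembly: shots, budgets and edit decision lists
#'
#' Per-frame labels (informative / branching / physician tags) are turned
#' into prioritized shots, and a frame budget derived from the compression
#' ratio and the minimum-summary-length floor decides which shots — whole,
#' truncated, or subsampled — enter the edit decision list.
#'
#' @name summarizer
NULL

PRIORITY_LEVELS <- c("annotation", "marker", "lesion", "branching",
                     "representative")

#' Summarization configuration
#'
#' @param ratio Source-to-summary length divisor. Default 12: one minute
#'   of source is represented by five seconds of summary.
#' @param min_summary_seconds Minimum summary duration in seconds
#'   (default 30); summaries shorter than this are not produced unless the
#'   source itself is shorter.
#' @param pad_frames Context padding added on both sides of tagged frame
#'   runs (default 12, about half a second at 25 fps).
#' @param merge_gap_frames Same-priority runs separated by fewer than this
#'   many frames are merged (default 12), provided the gap frames are
#'   informative.
#' @return A `bronch_summary_config` object.
#' @export
summary_config <- function(ratio = 12, min_summary_seconds = 30,
                           pad_frames = 12L, merge_gap_frames = 12L) {
  if (ratio <= 1) abort("`ratio` must be > 1")
  if (min_summary_seconds <= 0) abort("`min_summary_seconds` must be > 0")
  if (pad_frames < 0 || merge_gap_frames < 0) {
    abort("`pad_frames` and `merge_gap_frames` must be >= 0")
  }
  structure(list(ratio = ratio, min_summary_seconds = min_summary_seconds,
                 pad_frames = as.integer(pad_frames),
                 merge_gap_frames = as.integer(merge_gap_frames)),
            class = "bronch_summary_config")
}

#' Summary frame budget
#'
#' The budget is `frame_count / ratio`, raised to the minimum-summary
#' floor (`min_summary_seconds * fps`) when the ratio rule would undershoot
#' it; the floor itself is capped at the source length, so the budget never
#' exceeds the video.
#'
#' @param frame_count Number of source frames.
#' @param fps Source frame rate.
#' @param config A [summary_config()].
#' @return Integer frame budget.
#' @export
compute_budget <- function(frame_count, fps, config = summary_config()) {
  floor_frames <- min(config$min_summary_seconds * fps, frame_count)
  as.integer(round(max(frame_count / config$ratio, floor_frames)))
}

#' Assemble a per-frame label track
#'
#' @param informative Logical vector, one entry per frame.
#' @param branching Logical vector (same length).
#' @param marker,annotation,lesion Logical tag vectors (same length);
#'   default all-`FALSE`.
#' @return A `bronch_track` tibble with columns `frame`, `informative`,
#'   `branching`, `marker`, `annotation`, `lesion`.
#' @export
frame_label_track <- function(informative, branching = NULL, marker = NULL,
                              annotation = NULL, lesion = NULL) {
  n <- length(informative)
  fill <- function(x) if (is.null(x)) rep(FALSE, n) else x
  branching <- fill(branching); marker <- fill(marker)
  annotation <- fill(annotation); lesion <- fill(lesion)
  lens <- c(length(branching), length(marker), length(annotation),
            length(lesion))
  if (any(lens != n)) {
    abort(sprintf("track columns must all have length %d, got %s",
                  n, paste(lens, collapse = ", ")))
  }
  out <- tibble(frame = seq_len(n) - 1L,
                informative = as.logical(informative),
                branching = as.logical(branching),
                marker = as.logical(marker),
                annotation = as.logical(annotation),
                lesion = as.logical(lesion))
  structure(out, class = c("bronch_track", class(tibble())))
}

#' Merge classification, branching and annotation results into a track
#'
#' @param classified Output of [classify_frames()].
#' @param branching Output of [detect_branching()], or `NULL`.
#' @param annotations A [annotation_set()], or `NULL`.
#' @param keep_noninformative If `TRUE`, all frames are treated as
#'   informative (documented override; by default non-informative frames
#'   are excluded from summaries).
#' @return A `bronch_track` tibble.
#' @export
merge_label_track <- function(classified, branching = NULL,
                              annotations = NULL,
                              keep_noninformative = FALSE) {
  n <- nrow(classified)
  informative <- classified$label == "informative"
  if (keep_noninformative) informative <- rep(TRUE, n)
  br <- rep(FALSE, n)
  if (!is.null(branching)) br[branching$frame + 1L] <- branching$is_branching
  tags <- list(marker = rep(FALSE, n), annotation = rep(FALSE, n),
               lesion = rep(FALSE, n))
  if (!is.null(annotations) && nrow(annotations) > 0L) {
    if (any(annotations$frame >= n)) {
      abort("annotation frame index beyond video frame count")
    }
    for (i in seq_len(nrow(annotations))) {
      cls <- annotations$class[i]
      tags[[cls]][annotations$frame[i] + 1L] <- TRUE
    }
  }
  frame_label_track(informative, br, tags$marker, tags$annotation,
                    tags$lesion)
}

# Half-open 0-based runs of TRUE in a logical vector.
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}

# Expand TRUE runs by `pad` frames on each side (clipped to bounds).
pad_mask <- function(mask, pad) {
  if (pad == 0L || !any(mask)) return(mask)
  n <- length(mask)
  out <- rep(FALSE, n)
  r <- runs_of(mask)
  for (i in seq_len(nrow(r))) {
    a <- max(r$start[i] - pad, 0L); b <- min(r$end[i] + pad, n)
    out[(a + 1L):b] <- TRUE
  }
  out
}

# Bridge gaps between TRUE runs shorter than `gap` frames, but only where
# every gap frame is informative (exclusion outranks merging).
bridge_mask <- function(mask, gap, informative) {
  if (gap == 0L || !any(mask)) return(mask)
  r <- runs_of(mask)
  if (nrow(r) < 2L) return(mask)
  out <- mask
  for (i in seq_len(nrow(r) - 1L)) {
    a <- r$end[i]; b <- r$start[i + 1L]
    if (b - a < gap && all(informative[(a + 1L):b])) {
      out[(a + 1L):b] <- TRUE
    }
  }
  out
}

#' Build prioritized shots from a label track
#'
#' Non-informative frames are removed from candidacy. For each tag class,
#' maximal runs of tagged informative frames are padded by
#' `pad_frames` (padding never resurrects non-informative frames), and
#' same-class runs separated by fewer than `merge_gap_frames` informative
#' frames are merged. Each frame then takes its single highest-priority
#' class (annotation > marker > lesion > branching); remaining untagged
#' informative stretches become `representative` segments.
#'
#' @param track A [frame_label_track()].
#' @param config A [summary_config()].
#' @return A tibble of shots: `start`, `end` (half-open, 0-based),
#'   `priority`; sorted and pairwise disjoint.
#' @export
build_shots <- function(track, config = summary_config()) {
  stopifnot(inherits(track, "bronch_track"))
  n <- nrow(track)
  inf <- track$informative
  masks <- list()
  for (cls in c("annotation", "marker", "lesion", "branching")) {
    base <- track[[cls]] & inf
    m <- pad_mask(base, config$pad_frames) & inf
    masks[[cls]] <- bridge_mask(m, config$merge_gap_frames, inf)
  }
  priority <- rep(NA_character_, n)
  for (cls in c("annotation", "marker", "lesion", "branching")) {
    priority[is.na(priority) & masks[[cls]]] <- cls
  }
  priority[is.na(priority) & inf] <- "representative"

  r <- rle(priority)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- !is.na(r$values)
  tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]),
         priority = r$values[keep])
}

#' Construct / validate an edit decision list
#'
#' @param shots Tibble with columns `start`, `end` (half-open, 0-based
#'   frame intervals) and `priority`.
#' @param fps Source frame rate.
#' @param frame_count Source frame count.
#' @return A `bronch_edl` object (tibble with `fps` / `frame_count`
#'   attributes).
#' @export
edit_decision_list <- function(shots, fps, frame_count) {
  shots <- as_tibble(shots)[, c("start", "end", "priority")]
  if (nrow(shots) > 0L) {
    if (any(shots$start >= shots$end) || any(shots$start < 0) ||
        any(shots$end > frame_count)) {
      abort("shots must satisfy 0 <= start < end <= frame_count")
    }
    if (is.unsorted(shots$start, strictly = TRUE) ||
        any(shots$start[-1L] < shots$end[-nrow(shots)])) {
      abort("shots must be sorted by start and pairwise disjoint")
    }
    if (!all(shots$priority %in% PRIORITY_LEVELS)) {
      abort("unknown shot priority class")
    }
  }
  structure(shots, fps = fps, frame_count = as.integer(frame_count),
            class = c("bronch_edl", class(tibble())))
}

#' Total number of frames selected by an EDL
#' @param edl A `bronch_edl`.
#' @return Integer frame count.
#' @export
edl_length <- function(edl) as.integer(sum(edl$end - edl$start))

# Central sub-interval of `k` frames from [start, end).
central_sub <- function(start, end, k) {
  a <- start + ((end - start - k) %/% 2L)
  c(a, a + k)
}

# Largest-remainder apportionment of `rem` frames over segment lengths,
# one frame minimum per segment while the budget allows; capped at length.
alloc_representative <- function(len, rem) {
  n <- length(len)
  alloc <- integer(n)
  if (rem <= 0L || n == 0L) return(alloc)
  if (rem < n) { alloc[seq_len(rem)] <- 1L; return(alloc) }
  alloc <- rep(1L, n)
  rem <- rem - n
  cap <- pmax(len - 1L, 0L)
  while (rem > 0L && sum(cap) > 0L) {
    q <- cap / sum(cap) * rem
    add <- pmin(as.integer(floor(q)), cap)
    if (sum(add) == 0L) {
      ord <- order(-(q - floor(q)), seq_len(n))
      for (i in ord) {
        if (rem <= 0L) break
        if (cap[i] > 0L) {
          alloc[i] <- alloc[i] + 1L; cap[i] <- cap[i] - 1L; rem <- rem - 1L
        }
      }
    } else {
      alloc <- alloc + add; cap <- cap - add; rem <- rem - sum(add)
    }
  }
  alloc
}

#' Select shots into a budgeted edit decision list
#'
#' Priority classes are admitted in the order annotation, marker, lesion,
#' branching, each in temporal order, until the budget is exhausted; a
#' shot that would overflow the remaining budget is truncated symmetrically
#' about its center. When the tagged material alone exceeds the budget,
#' lesion shots longer than two seconds are first thinned to their central
#' two seconds. Any remaining budget is spread over the representative
#' segments by deterministic centered subsampling, proportional to segment
#' length with a one-frame minimum while the budget allows.
#'
#' @param shots Output of [build_shots()].
#' @param budget Frame budget from [compute_budget()].
#' @param fps Source frame rate (used for the two-second lesion rule).
#' @param frame_count Source frame count.
#' @param config A [summary_config()].
#' @return A `bronch_edl`.
#' @export
select_shots <- function(shots, budget, fps, frame_count,
                         config = summary_config()) {
  shots <- as_tibble(shots)
  prio <- dplyr::filter(shots, .data$priority != "representative")
  reps <- dplyr::filter(shots, .data$priority == "representative")

  if (sum(prio$end - prio$start) > budget) {
    two_s <- as.integer(round(2 * fps))
    for (i in which(prio$priority == "lesion" &
                    prio$end - prio$start > two_s)) {
      ab <- central_sub(prio$start[i], prio$end[i], two_s)
      prio$start[i] <- ab[1L]; prio$end[i] <- ab[2L]
    }
  }

  rem <- as.integer(budget)
  picked <- list()
  for (cls in c("annotation", "marker", "lesion", "branching")) {
    sub <- dplyr::arrange(dplyr::filter(prio, .data$priority == cls),
                          .data$start)
    for (i in seq_len(nrow(sub))) {
      if (rem <= 0L) break
      len <- sub$end[i] - sub$start[i]
      if (len <= rem) {
        picked[[length(picked) + 1L]] <- sub[i, ]
        rem <- rem - len
      } else {
        ab <- central_sub(sub$start[i], sub$end[i], rem)
        picked[[length(picked) + 1L]] <-
          tibble(start = ab[1L], end = ab[2L], priority = cls)
        rem <- 0L
      }
    }
  }

  if (rem > 0L && nrow(reps) > 0L) {
    reps <- dplyr::arrange(reps, .data$start)
    alloc <- alloc_representative(reps$end - reps$start, rem)
    for (i in seq_len(nrow(reps))) {
      if (alloc[i] > 0L) {
        ab <- central_sub(reps$start[i], reps$end[i], alloc[i])
        picked[[length(picked) + 1L]] <-
          tibble(start = ab[1L], end = ab[2L], priority = "representative")
      }
    }
  }

  out <- if (length(picked) == 0L) {
    tibble(start = integer(), end = integer(), priority = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(picked), .data$start)
  }
  edit_decision_list(out, fps = fps, frame_count = frame_count)
}

#' Summarize a label track into an edit decision list
#'
#' The pixel-free half of the pipeline: budget computation, shot building
#' and budgeted selection on an existing per-frame label track.
#'
#' @param track A [frame_label_track()].
#' @param fps Source frame rate.
#' @param config A [summary_config()].
#' @return A `bronch_edl`.
#' @export
summarize_track <- function(track, fps, config = summary_config()) {
  n <- nrow(track)
  budget <- compute_budget(n, fps, config)
  shots <- build_shots(track, config)
  select_shots(shots, budget, fps, n, config)
}

#' Summarize a video end to end
#'
#' Composes frame classification, branch detection (on informative frames
#' only: blur destroys the dark-region geometry), label merging with the
#' annotations, shot building, budgeting, and shot selection. Deterministic
#' for fixed inputs.
#'
#' @param video A [video_source()].
#' @param annotations A [annotation_set()] or `NULL`.
#' @param dct_model A [dct_detector()] model.
#' @param branch A [branch_params()] object.
#' @param config A [summary_config()].
#' @param keep_noninformative Documented override retaining non-informative
#'   frames as summary candidates (default `FALSE`).
#' @return A `bronch_edl`.
#' @export
summarize_video <- function(video, annotations = NULL,
                            dct_model = dct_detector(),
                            branch = branch_params(),
                            config = summary_config(),
                            keep_noninformative = FALSE) {
  stopifnot(inherits(video, "video_source"))
  classified <- classify_frames(video, dct_model)
  informative <- classified$label == "informative" | keep_noninformative
  has_ann <- !is.null(annotations) && nrow(annotations) > 0L
  if (!any(informative) && !has_ann) {
    warn("no informative frames and no annotations: summary is empty")
    return(edit_decision_list(
      tibble(start = integer(), end = integer(), priority = character()),
      fps = video$fps, frame_count = video$frame_count))
  }
  idx <- which(informative)
  branching <- tibble(frame = idx - 1L,
                      is_branching = vapply(idx, function(i) {
                        is_branching(segment_dark_regions(video$frames[[i]],
                                                          branch))
                      }, logical(1)))
  track <- merge_label_track(classified, branching, annotations,
                             keep_noninformative = keep_noninformative)
  summarize_track(track, video$fps, config)
}

#' Render an edit decision list to an image sequence
#'
#' Writes exactly the EDL's frames, in order, as `frame_%06d.png`
#' (renumbered from 0) under `out_dir`.
#'
#' @param video The source [video_source()].
#' @param edl A `bronch_edl` valid against `video`.
#' @param out_dir Output directory.
#' @return Invisibly, the number of frames written.
#' @export
render_summary <- function(video, edl, out_dir) {
  stopifnot(inherits(video, "video_source"), inherits(edl, "bronch_edl"))
  if (attr(edl, "frame_count") != video$frame_count) {
    abort("EDL frame count does not match the video")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(edl) == 0L) {
    warn(sprintf("empty EDL: no frames written to %s", out_dir))
    return(invisible(0L))
  }
  sel <- unlist(lapply(seq_len(nrow(edl)), function(i) {
    seq.int(edl$start[i], edl$end[i] - 1L)
  }))
  write_frames(video$frames[sel + 1L], out_dir)
  invisible(length(sel))
}
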