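test_that("frame budget follows the ratio rule with a capped floor", {
  cfg <- summary_config()
  # the ratio rule: one source minute -> five summary seconds, realized
  # whenever the floor is inactive (here: ten minutes -> fifty seconds)
  expect_equal(compute_budget(600 * 25, 25, cfg), 1250L)
  # short sources are raised to the 30-second floor
  expect_equal(compute_budget(1500, 25, cfg), 750L)
  # five minutes: ratio rule would give 25 s, floor raises it to 30 s
  expect_equal(compute_budget(7500, 25, cfg), 750L)
  # ten-second source: floor capped at the source length
  expect_equal(compute_budget(250, 25, cfg), 250L)
  # budget never exceeds the source
  for (n in c(10, 100, 10000)) {
    expect_lte(compute_budget(n, 25, cfg), n)
  }
})

test_that("build_shots pads, merges and prioritizes as specified", {
  n <- 400
  # all frames non-informative, no tags -> no shots
  t0 <- frame_label_track(rep(FALSE, n))
  expect_equal(nrow(build_shots(t0)), 0)

  # one annotated frame at index 100, pad 12 -> [88, 113)
  ann <- rep(FALSE, n); ann[101] <- TRUE
  t1 <- frame_label_track(rep(TRUE, n), annotation = ann)
  s1 <- build_shots(t1)
  a1 <- s1[s1$priority == "annotation", ]
  expect_equal(c(a1$start, a1$end), c(88L, 113L))

  # branching runs [200,210) and [214,220), merge gap 5 -> [200, 220)
  br <- rep(FALSE, n); br[201:210] <- TRUE; br[215:220] <- TRUE
  t2 <- frame_label_track(rep(TRUE, n), branching = br)
  s2 <- build_shots(t2, summary_config(pad_frames = 0, merge_gap_frames = 5))
  b2 <- s2[s2$priority == "branching", ]
  expect_equal(c(b2$start, b2$end), c(200L, 220L))

  # gap frames that are non-informative block the merge
  inf <- rep(TRUE, n); inf[212] <- FALSE
  t3 <- frame_label_track(inf, branching = br)
  s3 <- build_shots(t3, summary_config(pad_frames = 0, merge_gap_frames = 5))
  expect_equal(sum(s3$priority == "branching"), 2)

  # padding never resurrects non-informative frames: the non-informative
  # gap (0-based 94..96) splits the padded window, both informative parts
  # survive as annotation shots
  inf2 <- rep(TRUE, n); inf2[95:97] <- FALSE
  t4 <- frame_label_track(inf2, annotation = ann)
  s4 <- build_shots(t4)
  a4 <- s4[s4$priority == "annotation", ]
  expect_equal(a4$start, c(88L, 97L))
  expect_equal(a4$end, c(94L, 113L))

  # priority resolution: annotation outranks overlapping branching
  both <- frame_label_track(rep(TRUE, n), branching = ann, annotation = ann)
  s5 <- build_shots(both)
  expect_false("branching" %in% s5$priority)
  expect_true("annotation" %in% s5$priority)
})

test_that("track length mismatches are rejected", {
  expect_error(frame_label_track(rep(TRUE, 10), branching = rep(FALSE, 5)),
               "length 10")
})

test_that("select_shots honours slack budgets, priorities and truncation", {
  fps <- 25
  shots <- tibble::tibble(
    start = c(10L, 100L, 200L), end = c(60L, 150L, 300L),
    priority = c("annotation", "representative", "representative"))
  # slack budget: everything admitted unchanged
  edl <- select_shots(shots, 1000L, fps, 400L)
  expect_equal(shot_tbl(edl)[, c("start", "end")],
               shots[, c("start", "end")])

  # tight budget: the annotation shot exactly fills it
  edl2 <- select_shots(shots, 50L, fps, 400L)
  expect_equal(nrow(edl2), 1)
  expect_equal(edl2$priority, "annotation")
  expect_equal(edl_length(edl2), 50L)

  # two 40-frame annotation shots, budget 60: second truncated centrally
  shots3 <- tibble::tibble(start = c(0L, 100L), end = c(40L, 140L),
                           priority = "annotation")
  edl3 <- select_shots(shots3, 60L, fps, 400L)
  expect_equal(shot_tbl(edl3),
               tibble::tibble(start = c(0L, 110L), end = c(40L, 130L),
                              priority = c("annotation", "annotation")))
})

test_that("long lesion shots are thinned to their central two seconds", {
  fps <- 25
  shots <- tibble::tibble(
    start = c(0L, 200L), end = c(150L, 500L),
    priority = c("lesion", "representative"))
  # over budget: 150-frame lesion shot becomes its central 50 frames
  edl <- select_shots(shots, 80L, fps, 600L)
  les <- as_tibble(edl)[edl$priority == "lesion", ]
  expect_equal(c(les$start, les$end), c(50L, 100L))
  # under budget: left whole
  edl2 <- select_shots(shots, 1000L, fps, 600L)
  les2 <- as_tibble(edl2)[edl2$priority == "lesion", ]
  expect_equal(c(les2$start, les2$end), c(0L, 150L))
})

test_that("representative allocation is proportional with one-frame floor", {
  fps <- 25
  shots <- tibble::tibble(start = c(0L, 100L, 400L),
                          end = c(60L, 160L, 520L),
                          priority = "representative")
  edl <- select_shots(shots, 60L, fps, 600L)
  expect_equal(edl_length(edl), 60L)
  lens <- edl$end - edl$start
  # 60/240, 60/240, 120/240 of 60 -> 15, 15, 30
  expect_equal(lens, c(15L, 15L, 30L))
  # centered inside each segment
  expect_true(all(edl$start >= shots$start & edl$end <= shots$end))

  # budget smaller than segment count: first segments get one frame each
  edl2 <- select_shots(shots, 2L, fps, 600L)
  expect_equal(edl_length(edl2), 2L)
  expect_equal(edl2$end - edl2$start, c(1L, 1L))
})

test_that("summarizer invariants hold on random label tracks", {
  cfg <- summary_config(min_summary_seconds = 4)
  for (seed in 1:50) {
    track <- random_track(seed, n = 600)
    edl <- summarize_track(track, fps = 25, cfg)
    budget <- compute_budget(600, 25, cfg)
    expect_edl_valid(edl, track, budget, cfg)

    # priority dominance: annotation material is fully included before
    # any lower-priority frames are admitted
    shots <- build_shots(track, cfg)
    total_ann <- sum(with(shots, end - start)[shots$priority == "annotation"])
    in_ann <- sum(with(edl, end - start)[edl$priority == "annotation"])
    lower <- edl_length(edl) - in_ann
    if (lower > 0) expect_equal(in_ann, min(total_ann, budget))

    # determinism
    expect_identical(edl, summarize_track(track, fps = 25, cfg))
  }
})

test_that("empty videos summarize to an empty EDL with a warning", {
  frames <- replicate(12, matrix(120, 16, 16), simplify = FALSE)
  video <- video_source(frames, fps = 25)
  model <- dct_detector(working_size = 16, decision_threshold = 0.5)
  expect_warning(edl <- summarize_video(video, dct_model = model),
                 "empty")
  expect_equal(nrow(edl), 0)
})

test_that("render_summary copies exactly the EDL frames in order", {
  withr::with_seed(41, {
    frames <- lapply(1:20, function(i) {
      matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    })
  })
  video <- video_source(frames, fps = 25)
  edl <- edit_decision_list(
    tibble::tibble(start = c(2L, 15L), end = c(7L, 20L),
                   priority = c("lesion", "representative")),
    fps = 25, frame_count = 20)
  out <- withr::local_tempdir()
  n <- render_summary(video, edl, out)
  expect_equal(n, 10L)
  rendered <- read_video(out)
  expect_equal(rendered$frame_count, 10)
  src <- c(3:7, 16:20)
  for (i in seq_along(src)) {
    expect_equal(rendered$frames[[i]], frames[[src[i]]], tolerance = 1e-6)
  }

  # whole-video EDL reproduces the source frame count
  whole <- edit_decision_list(
    tibble::tibble(start = 0L, end = 20L, priority = "representative"),
    fps = 25, frame_count = 20)
  out2 <- withr::local_tempdir()
  expect_equal(render_summary(video, whole, out2), 20L)

  # empty EDL -> warning, nothing written
  empty <- edit_decision_list(
    tibble::tibble(start = integer(), end = integer(),
                   priority = character()), fps = 25, frame_count = 20)
  out3 <- withr::local_tempdir()
  expect_warning(render_summary(video, empty, out3), "empty")
  expect_equal(length(list.files(out3)), 0)
})
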