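test_that("dct2 matches the naive double-sum DCT-II oracle exactly", {
  withr::with_seed(101, {
    for (n in c(8L, 16L)) {
      for (k in 1:5) {
        x <- matrix(runif(n * n, 0, 255), n, n)
        expect_equal(dct2(x), naive_dct2(x), tolerance = 1e-9)
      }
    }
  })
})

test_that("non-zero fraction equals the oracle count on random matrices", {
  model8 <- dct_detector(working_size = 8)
  model16 <- dct_detector(working_size = 16)
  withr::with_seed(102, {
    for (k in 1:25) {
      x8 <- matrix(runif(64, 0, 255), 8, 8)
      expect_identical(dct_nonzero_fraction(x8, model8) * 64,
                       as.numeric(naive_nonzero_count(x8)))
      x16 <- matrix(runif(256, 0, 255), 16, 16)
      expect_identical(dct_nonzero_fraction(x16, model16) * 256,
                       as.numeric(naive_nonzero_count(x16)))
    }
  })
})

test_that("integer ramp image matches the oracle count", {
  ramp <- matrix(rep(seq(0, 255, length.out = 8), each = 8), 8, 8)
  model <- dct_detector(working_size = 8)
  expect_equal(dct_nonzero_fraction(ramp, model) * 64,
               naive_nonzero_count(ramp))
})

test_that("constant frames keep at most the DC coefficient", {
  model <- dct_detector(working_size = 32)
  for (v in c(0, 100, 255)) {
    expect_lte(dct_nonzero_fraction(matrix(v, 32, 32), model), 1 / 32^2)
  }
})

test_that("Gaussian blur strictly reduces the non-zero fraction", {
  model <- dct_detector()
  for (seed in 1:5) {
    base <- make_informative_frame(seed, 128, 1)$frame
    blurred <- make_noninformative_frame(base, 8)
    expect_lt(dct_nonzero_fraction(blurred, model),
              dct_nonzero_fraction(base, model))
  }
})

test_that("fraction is non-increasing in blur sigma on fixture frames", {
  model <- dct_detector(working_size = 128)
  sigmas <- c(2, 4, 6, 8, 12)
  for (seed in 1:5) {
    base <- make_informative_frame(100 + seed, 128, 1)$frame
    fr <- vapply(sigmas, function(s) {
      dct_nonzero_fraction(make_noninformative_frame(base, s), model)
    }, numeric(1))
    expect_true(all(diff(fr) <= 0))
  }
})

test_that("classification threshold uses the stated tie-break", {
  model <- dct_detector(decision_threshold = 0.3)
  expect_equal(classify_fraction(0, model), "non_informative")
  expect_equal(classify_fraction(1, model), "informative")
  expect_equal(classify_fraction(0.3, model), "informative")  # tie
  expect_equal(classify_fraction(0.3 - 1e-9, model), "non_informative")
})

test_that("classification label survives aspect-ratio distortion", {
  model <- dct_detector(working_size = 128, decision_threshold = 0.2)
  for (seed in 1:3) {
    base <- make_informative_frame(200 + seed, 128, 1)$frame
    wide <- base[, rep(seq_len(128), each = 2)]  # 128 x 256
    expect_equal(
      classify_fraction(dct_nonzero_fraction(wide, model), model),
      classify_fraction(dct_nonzero_fraction(base, model), model))
    blur <- make_noninformative_frame(base, 10)
    blur_wide <- blur[, rep(seq_len(128), each = 2)]
    expect_equal(
      classify_fraction(dct_nonzero_fraction(blur_wide, model), model),
      classify_fraction(dct_nonzero_fraction(blur, model), model))
  }
})

test_that("threshold training maximizes F-measure with larger-tie-break", {
  # separable case: training F-measure is 1
  fit <- train_decision_threshold(
    c(0.05, 0.1, 0.6, 0.7, 0.8, 0.9),
    c(rep("non_informative", 2), rep("informative", 4)), split_seed = NULL)
  expect_equal(
    fit$train_metrics$value[fit$train_metrics$metric == "f_measure"], 1)
  expect_gt(fit$threshold, 0.1)
  expect_lte(fit$threshold, 0.6)

  # four-point case: the optimum lies in (0.2, 0.3]
  frac <- c(0.1, 0.2, 0.3, 0.4)
  lab <- c("non_informative", "non_informative", "informative",
           "informative")
  fit2 <- train_decision_threshold(frac, lab, split_seed = NULL)
  expect_gt(fit2$threshold, 0.2)
  expect_lte(fit2$threshold, 0.3)
  # exhaustive sweep oracle: no threshold beats the chosen one
  grid <- c(seq(0, 1, by = 0.001), fit2$threshold)
  best <- max(vapply(grid, sweep_f_measure, numeric(1), frac, lab))
  expect_equal(sweep_f_measure(fit2$threshold, frac, lab), best)
})

test_that("threshold training is deterministic and validates inputs", {
  withr::with_seed(103, {
    frac <- c(runif(20, 0, 0.3), runif(20, 0.4, 1))
    lab <- rep(c("non_informative", "informative"), each = 20)
  })
  f1 <- train_decision_threshold(frac, lab, split_seed = 7)
  f2 <- train_decision_threshold(frac, lab, split_seed = 7)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$test_metrics, f2$test_metrics)
  expect_error(train_decision_threshold(frac, rep("informative", 40)),
               "each class")
})

test_that("DCT models persist as JSON", {
  m <- dct_detector(20, 0.317, 256)
  path <- withr::local_tempfile(fileext = ".json")
  save_dct_model(m, path)
  expect_identical(load_dct_model(path), m)
})
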