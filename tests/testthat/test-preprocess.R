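test_that("ENMO is the Euclidean norm minus one, with optional truncation", {
  rec <- makeRecording(x = c(0, 1, 0.3, 0.6), y = c(0, 2, 0.4, 0.8),
                       z = c(1, 2, 0, 0))
  raw <- computeEnmo(rec, truncate = FALSE)
  expect_equal(enmoValues(raw), c(0, 2, -0.5, 0))
  expect_false(raw@truncated)
  trunc <- computeEnmo(rec, truncate = TRUE)
  expect_equal(enmoValues(trunc), c(0, 2, 0, 0))
  expect_true(trunc@truncated)
})

test_that("unit-norm recordings have identically zero ENMO", {
  set.seed(101)
  for (i in 1:50) {
    v <- matrix(rnorm(3 * 40), 40, 3)
    v <- v / sqrt(rowSums(v^2))
    rec <- makeRecording(v[, 1], v[, 2], v[, 3])
    expect_lt(max(abs(enmoValues(computeEnmo(rec)))), 1e-9)
  }
})

test_that("per-second sums aggregate whole seconds and drop partial tails", {
  expect_equal(perSecondSums(makeEnmo(rep(0.05, 100), fs = 100)), 5.0)
  expect_equal(perSecondSums(makeEnmo(rep(0, 300), fs = 100)), c(0, 0, 0))
  expect_warning(
    s <- perSecondSums(makeEnmo(rep(1, 150), fs = 100)), "partial")
  expect_equal(s, 100)
  expect_error(perSecondSums(makeEnmo(rep(1, 50), fs = 100)), "second")
})

test_that("labels follow the cut-points with the stated boundary rules", {
  expect_identical(windowLabel(5), "SD")
  expect_identical(windowLabel(20), "LPA")
  expect_identical(windowLabel(60), "MVPA")
  # boundaries: 10 enters the light band, 42 stays in it, above 42 is MVPA
  expect_identical(windowLabel(10), "LPA")
  expect_identical(windowLabel(42), "LPA")
  expect_identical(windowLabel(42 + 1e-6), "MVPA")
  expect_identical(windowLabel(10 - 1e-6), "SD")
  expect_error(windowLabel(numeric(0)), "at least one")
  expect_error(windowLabel(c(5, -1)), "nonnegative")
  # custom cut-points
  th <- intensityThresholds(sdUpper = 1, lpaUpper = 2)
  expect_identical(windowLabel(1.5, th), "LPA")
})

test_that("segmentation yields floor(N / (tw*fs)) windows in time order", {
  enmo <- makeEnmo(runif(350), fs = 100)
  ws <- segmentWindows(enmo, 1L)
  expect_equal(nObs(ws), 3L)
  expect_equal(ws@startTime, c(0, 1, 2))
  expect_equal(ws@samples[2, ], enmo@values[101:200])

  for (n in c(100, 550, 990, 3000)) {
    for (tw in c(1L, 5L)) {
      ws <- suppressWarnings(segmentWindows(makeEnmo(runif(n), fs = 100), tw))
      expect_equal(nObs(ws), n %/% (tw * 100))
    }
  }
  expect_warning(
    empty <- segmentWindows(makeEnmo(runif(120), fs = 100), 5L), "shorter")
  expect_equal(nObs(empty), 0L)
})

test_that("simulated windows get the labels their targets dictate", {
  sc <- activityScript(30L, 60, noiseSd = 0, seed = 3L)
  ws <- segmentWindows(computeEnmo(generateRecording(sc, fs = 100L)), 30L)
  expect_equal(nObs(ws), 1L)
  expect_identical(as.character(classLabels(ws)), "MVPA")

  sc2 <- activityScript(c(10L, 10L), c(5, 60), noiseSd = 0, seed = 3L)
  ws2 <- segmentWindows(computeEnmo(generateRecording(sc2, fs = 100L)), 10L)
  expect_identical(as.character(classLabels(ws2)), c("SD", "MVPA"))
})

test_that("a constant-intensity signal keeps its label at every window length", {
  sc <- activityScript(30L, 20, noiseSd = 0, seed = 8L)
  enmo <- computeEnmo(generateRecording(sc, fs = 100L))
  for (tw in c(1L, 5L, 10L, 15L, 30L)) {
    ws <- segmentWindows(enmo, tw)
    expect_true(all(classLabels(ws) == "LPA"),
                info = sprintf("tw = %d", tw))
  }
})

test_that("window label CSV export has the documented columns", {
  sc <- activityScript(4L, 20, noiseSd = 0, seed = 2L)
  ws <- segmentWindows(computeEnmo(generateRecording(sc, fs = 50L)), 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeWindowLabels(ws, path)
  df <- read.csv(path)
  expect_named(df, c("start_time", "tw_s", "label", "mean_per_second_sum"))
  expect_equal(df$mean_per_second_sum, c(20, 20), tolerance = 1e-9)
})
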