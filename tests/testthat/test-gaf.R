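test_that("min-max normalisation maps to [-1, 1] with the degenerate rule", {
  expect_equal(minmaxNormalize(c(0, 5, 10)), c(-1, 0, 1))
  expect_equal(minmaxNormalize(c(2, 4, 4, 3)), c(-1, 1, 1, 0))
  expect_warning(out <- minmaxNormalize(c(0, 0, 0)), "constant")
  expect_equal(out, c(-1, -1, -1))
  expect_error(minmaxNormalize(numeric(0)), "empty")
})

test_that("polar mapping uses arccos angles and normalised time radii", {
  p <- toPolar(1)
  expect_equal(p$theta, 0)
  expect_equal(p$r, 1)
  p3 <- toPolar(c(-1, 0, 1))
  expect_equal(p3$theta, c(pi, pi / 2, 0))
  expect_equal(p3$r, c(1 / 3, 2 / 3, 1))
  expect_equal(toPolar(0.5)$theta, acos(0.5))
  # clip within tolerance, reject beyond it
  expect_equal(toPolar(1 + 1e-12)$theta, 0)
  expect_error(toPolar(1.01), "\\[-1, 1\\]")
})

test_that("gafMatrix matches the brute-force double loop", {
  expect_equal(gafMatrix(toPolar(1)), matrix(1, 1, 1))
  expect_equal(gafMatrix(toPolar(c(1, -1))),
               matrix(c(1, -1, -1, 1), 2, 2))
  set.seed(11)
  for (rep in 1:5) {
    vt <- runif(64, -1, 1)
    G <- gafMatrix(toPolar(vt))
    theta <- acos(vt)
    oracle <- matrix(0, 64, 64)
    for (i in 1:64) for (j in 1:64) oracle[i, j] <- cos(theta[i] + theta[j])
    expect_lt(max(abs(G - oracle)), 1e-12)
    expect_identical(G, t(G))
    expect_lt(max(abs(diag(G) - (2 * vt^2 - 1))), 1e-9)
    expect_true(all(G >= -1 - 1e-12 & G <= 1 + 1e-12))
  }
})

test_that("the [0, 1] rescale is the fixed affine map", {
  expect_equal(rescale01(matrix(c(1, -1, -1, 1), 2)), matrix(c(1, 0, 0, 1), 2))
  expect_equal(rescale01(matrix(0, 3, 3)), matrix(0.5, 3, 3))
  set.seed(2)
  G <- matrix(runif(25, -1, 1), 5)
  expect_lt(max(abs(rescale01(G) - (G + 1) / 2)), 1e-15)
})

test_that("rendering quantises to 8 bits and resizes bilinearly", {
  # native resolution: no interpolation, pure quantisation
  set.seed(3)
  G01 <- matrix(runif(224 * 224), 224)
  img <- renderImage(G01, 224L)
  expect_equal(dim(img@pixels), c(224, 224, 3))
  expect_equal(img@pixels[, , 1], floor(255 * G01 + 0.5))
  expect_identical(img@pixels[, , 1], img@pixels[, , 3])

  # constant matrix at any size: all pixels 128 (round half up)
  expect_true(all(renderImage(matrix(0.5, 7, 7), 16L)@pixels == 128))

  # 2x2 checkerboard upsampled to 4x4 vs an independent per-pixel oracle
  M <- matrix(c(0, 1, 1, 0), 2)
  img4 <- renderImage(M, 4L)
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) {
    for (j in 1:4) {
      xi <- min(max((i - 0.5) * 2 / 4 - 0.5, 0), 1)
      xj <- min(max((j - 0.5) * 2 / 4 - 0.5, 0), 1)
      i0 <- floor(xi); j0 <- floor(xj)
      wi <- xi - i0; wj <- xj - j0
      i1 <- min(i0 + 1, 1); j1 <- min(j0 + 1, 1)
      val <- M[i0 + 1, j0 + 1] * (1 - wi) * (1 - wj) +
        M[i0 + 1, j1 + 1] * (1 - wi) * wj +
        M[i1 + 1, j0 + 1] * wi * (1 - wj) +
        M[i1 + 1, j1 + 1] * wi * wj
      oracle[i, j] <- floor(255 * val + 0.5)
    }
  }
  expect_true(max(abs(img4@pixels[, , 1] - oracle)) <= 1)
  expect_error(renderImage(M, 1L), "resolution")
})

test_that("the full encoding keeps every stage in range and symmetric", {
  set.seed(5)
  for (rep in 1:10) {
    v <- pmax(rnorm(80, 0.3, 0.4), 0)
    vt <- minmaxNormalize(v)
    expect_true(all(vt >= -1 & vt <= 1))
    pol <- toPolar(vt)
    expect_true(all(pol$theta >= 0 & pol$theta <= pi))
    G <- gafMatrix(pol)
    expect_true(all(abs(G) <= 1 + 1e-12))
    img <- renderImage(rescale01(G), 80L)
    px <- img@pixels[, , 1]
    expect_true(all(px >= 0 & px <= 255))
    expect_identical(px, t(px))  # symmetry preserved at native resolution
  }
})

test_that("identical windows give byte-identical PNGs", {
  sc <- activityScript(2L, 20, noiseSd = 0.01, seed = 21L)
  ws <- segmentWindows(computeEnmo(generateRecording(sc, fs = 100L)), 1L)
  img <- gafEncode(ws, resolution = 32L)[[1]]
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  writeGafPng(img, p1)
  writeGafPng(img, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("sequence building groups consecutive windows with majority labels", {
  sc <- activityScript(c(3L, 1L, 4L), c(5, 60, 60), noiseSd = 0, seed = 6L)
  ws <- segmentWindows(computeEnmo(generateRecording(sc, fs = 50L)), 1L)
  sq <- buildSequences(ws, seqLen = 4L, resolution = 16L)
  expect_equal(nObs(sq), 2L)
  # first run: SD SD SD MVPA -> SD; second run: all MVPA
  expect_identical(as.character(classLabels(sq)), c("SD", "MVPA"))
  expect_equal(dim(sq@images), c(2, 4, 16, 16))
})

test_that("a tied run takes the label of its most recent member", {
  expect_identical(actigaf:::majorityLabel(c("SD", "SD", "MVPA", "MVPA")),
                   "MVPA")
  expect_identical(actigaf:::majorityLabel(c("MVPA", "LPA", "LPA", "MVPA")),
                   "MVPA")
  expect_identical(actigaf:::majorityLabel(c("SD", "SD", "MVPA", "LPA")),
                   "SD")
})

test_that("the GAF directory tree and index are written as documented", {
  sc <- activityScript(c(2L, 2L), c(5, 60), noiseSd = 0, seed = 31L)
  ws <- segmentWindows(computeEnmo(generateRecording(sc, fs = 50L)), 2L)
  out <- withr::local_tempdir()
  idx <- writeGafTree(ws, out, resolution = 16L)
  expect_true(file.exists(file.path(out, "index.csv")))
  expect_equal(nrow(idx), 2L)
  expect_true(all(file.exists(idx$path)))
  expect_match(idx$path[1], "2s/SD", fixed = TRUE)
  expect_match(idx$path[2], "2s/MVPA", fixed = TRUE)
})
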