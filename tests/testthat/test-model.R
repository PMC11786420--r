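ns <- asNamespace("actigaf")

test_that("patch grids follow the (imageSize / patchSize)^2 arithmetic", {
  m <- vitBilstm(imageSize = 32L, patchSize = 8L, embedDim = 8L, depth = 1L,
                 heads = 2L, hiddenSize = 4L, seed = 1L)
  expect_equal(numPatches(m), 16L)
  expect_equal(numPatches(vitBilstm(tiny = TRUE, seed = 1L)), 64L)
  expect_error(vitBilstm(imageSize = 30L, patchSize = 8L), "divisible")
})

test_that("a zero image with zero patch projection embeds to the positional codes", {
  m <- vitBilstm(imageSize = 8L, patchSize = 4L, embedDim = 6L, depth = 0L,
                 heads = 2L, hiddenSize = 2L, seed = 1L,
                 normMean = 0, normStd = 1)
  m@params[["patch.W"]][] <- 0
  m@params[["cls"]][] <- 0
  f <- vitFeatures(m, array(0, dim = c(1, 8, 8)))
  # with depth 0 the class-token feature is exactly its positional encoding
  expect_equal(as.numeric(f), as.numeric(m@params[["pos"]][1, ]))
})

test_that("with zeroed positional codes the class token ignores patch order", {
  m <- vitBilstm(imageSize = 16L, patchSize = 8L, embedDim = 8L, depth = 2L,
                 heads = 2L, hiddenSize = 4L, seed = 5L)
  m@params[["pos"]][] <- 0
  set.seed(6)
  img <- array(runif(16 * 16, 0, 255), dim = c(1, 16, 16))
  # swapping two patch blocks permutes the token sequence
  img2 <- img
  img2[1, 1:8, 1:8] <- img[1, 1:8, 9:16]
  img2[1, 1:8, 9:16] <- img[1, 1:8, 1:8]
  f1 <- vitFeatures(m, img)
  f2 <- vitFeatures(m, img2)
  expect_equal(f1, f2, tolerance = 1e-10)
  # with positional codes restored the order matters again
  m2 <- vitBilstm(imageSize = 16L, patchSize = 8L, embedDim = 8L, depth = 2L,
                  heads = 2L, hiddenSize = 4L, seed = 5L)
  expect_gt(max(abs(vitFeatures(m2, img) - vitFeatures(m2, img2))), 1e-6)
})

test_that("feature dimensions follow the configuration", {
  m <- vitBilstm(tiny = TRUE, seed = 2L)
  set.seed(7)
  imgs <- array(runif(2 * 64 * 64, 0, 255), dim = c(2, 64, 64))
  f <- vitFeatures(m, imgs)
  expect_equal(dim(f), c(2L, 32L))
  # identical calls are bit-identical; batching only perturbs rounding
  expect_identical(f, vitFeatures(m, imgs))
  expect_equal(f[1, ], vitFeatures(m, imgs[1, , , drop = FALSE])[1, ],
               tolerance = 1e-10)
  h <- bilstmFeatures(m, matrix(rnorm(4 * 32), 4, 32))
  expect_equal(dim(h), c(1L, 64L))
  # a length-1 sequence is still valid
  h1 <- bilstmFeatures(m, matrix(rnorm(32), 1, 32))
  expect_equal(dim(h1), c(1L, 64L))
})

test_that("bilstm recurrence matches a manual LSTM on a small example", {
  m <- vitBilstm(imageSize = 8L, patchSize = 4L, embedDim = 2L, depth = 1L,
                 heads = 1L, hiddenSize = 1L, numLayers = 1L, seqLen = 2L,
                 seed = 9L)
  x <- matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2, byrow = TRUE)  # two steps
  sig <- function(z) 1 / (1 + exp(-z))
  step <- function(xt, h, c, Wx, Wh, b) {
    z <- as.numeric(xt %*% Wx) + as.numeric(h %*% Wh) + b
    i <- sig(z[1]); f <- sig(z[2]); g <- tanh(z[3]); o <- sig(z[4])
    c2 <- f * c + i * g
    list(h = o * tanh(c2), c = c2)
  }
  p <- m@params
  fw1 <- step(x[1, , drop = FALSE], 0, 0, p[["lstm1.f.Wx"]], p[["lstm1.f.Wh"]],
              p[["lstm1.f.b"]])
  fw2 <- step(x[2, , drop = FALSE], fw1$h, fw1$c, p[["lstm1.f.Wx"]],
              p[["lstm1.f.Wh"]], p[["lstm1.f.b"]])
  bw1 <- step(x[2, , drop = FALSE], 0, 0, p[["lstm1.b.Wx"]], p[["lstm1.b.Wh"]],
              p[["lstm1.b.b"]])
  bw2 <- step(x[1, , drop = FALSE], bw1$h, bw1$c, p[["lstm1.b.Wx"]],
              p[["lstm1.b.Wh"]], p[["lstm1.b.b"]])
  h <- bilstmFeatures(m, x)
  expect_equal(as.numeric(h), c(fw2$h, bw2$h), tolerance = 1e-12)
})

test_that("with shared direction weights, reversing the input swaps the halves", {
  m <- vitBilstm(imageSize = 8L, patchSize = 4L, embedDim = 3L, depth = 1L,
                 heads = 1L, hiddenSize = 2L, numLayers = 1L, seqLen = 3L,
                 seed = 10L)
  for (w in c("Wx", "Wh", "b")) {
    m@params[[sprintf("lstm1.b.%s", w)]] <- m@params[[sprintf("lstm1.f.%s", w)]]
  }
  x <- matrix(rnorm(9), 3, 3)
  h <- as.numeric(bilstmFeatures(m, x))
  hRev <- as.numeric(bilstmFeatures(m, x[3:1, ]))
  expect_equal(hRev, c(h[3:4], h[1:2]), tolerance = 1e-12)
})

test_that("classification returns a proper probability simplex", {
  m <- vitBilstm(tiny = TRUE, seed = 3L)
  ds <- simulateIntensityDataset(nPerClass = 2L, resolution = 64L, seed = 3L)
  res <- classify(m, ds)
  expect_equal(rowSums(res$prob), rep(1, nObs(ds)), tolerance = 1e-6)
  expect_true(all(res$prob >= 0))
  expect_identical(as.character(res$label),
                   intensityLevels()[max.col(res$prob, "first")])
  # eval-mode determinism
  res2 <- classify(m, ds)
  expect_identical(res$prob, res2$prob)

  # zero head: exactly uniform probabilities
  m0 <- m
  m0@params[["head.W"]][] <- 0
  m0@params[["head.b"]][] <- 0
  expect_equal(unname(classify(m0, ds)$prob),
               matrix(1 / 3, nObs(ds), 3), tolerance = 1e-12)
  # dominant logit saturates the softmax
  mBig <- m0
  mBig@params[["head.b"]] <- c(50, 0, 0)
  expect_equal(unname(classify(mBig, ds)$prob[, 1]), rep(1, nObs(ds)),
               tolerance = 1e-12)
})

test_that("sequence/model mismatches are rejected", {
  m <- vitBilstm(tiny = TRUE, seed = 1L)
  ds <- smallDataset(nPerClass = 2L, resolution = 16L)
  expect_error(classify(m, ds), "image size")
  ds64 <- simulateIntensityDataset(nPerClass = 2L, resolution = 64L,
                                   seqLen = 2L, seed = 1L)
  expect_error(classify(m, ds64), "sequence length")
})

test_that("analytic gradients agree with central finite differences", {
  m <- gradcheckModel()
  set.seed(42)
  images <- array(runif(2 * 2 * 8 * 8, 0, 255), dim = c(2, 2, 8, 8))
  y <- c(1L, 3L)
  lossFor <- function(model) {
    fw <- ns$nnForward(model, images)
    ns$crossEntropy(fw$prob, y)
  }
  fw <- ns$nnForward(m, images, keepCache = TRUE)
  grads <- ns$nnBackward(m, fw$cache, ns$crossEntropyGrad(fw$prob, y))
  h <- 1e-5
  set.seed(7)
  for (nm in names(m@params)) {
    p <- m@params[[nm]]
    for (i in sample.int(length(p), min(length(p), 4L))) {
      mp <- m; mp@params[[nm]][i] <- p[i] + h
      mm <- m; mm@params[[nm]][i] <- p[i] - h
      num <- (lossFor(mp) - lossFor(mm)) / (2 * h)
      rel <- abs(num - grads[[nm]][i]) /
        max(1e-6, abs(num) + abs(grads[[nm]][i]))
      expect_lt(rel, 1e-3)
    }
  }
})

test_that("one Adam step on a batch lowers that batch's loss", {
  m <- gradcheckModel(seed = 21L)
  set.seed(22)
  images <- array(runif(4 * 2 * 8 * 8, 0, 255), dim = c(4, 2, 8, 8))
  y <- c(1L, 2L, 3L, 1L)
  fw <- ns$nnForward(m, images, keepCache = TRUE)
  l0 <- ns$crossEntropy(fw$prob, y)
  grads <- ns$nnBackward(m, fw$cache, ns$crossEntropyGrad(fw$prob, y))
  cfg <- trainConfig(lr = 1e-3, weightDecay = 0)
  state <- list(t = 0L, m = lapply(m@params, function(p) p * 0),
                v = lapply(m@params, function(p) p * 0))
  upd <- ns$adamStep(m@params, grads, state, 1e-3, cfg)
  m@params <- upd$params
  l1 <- ns$crossEntropy(ns$nnForward(m, images)$prob, y)
  expect_lt(l1, l0)
})

test_that("models survive a save/load round trip", {
  m <- vitBilstm(imageSize = 16L, patchSize = 8L, embedDim = 8L, depth = 1L,
                 heads = 2L, hiddenSize = 4L, seed = 12L)
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(m2@config$embedDim, m@config$embedDim)
  set.seed(13)
  img <- array(runif(16 * 16, 0, 255), dim = c(1, 16, 16))
  expect_identical(vitFeatures(m, img), vitFeatures(m2, img))
})
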