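# Shared fixtures, built in code at test time.

# A recording constructed directly from given axis vectors (fs chosen so
# the one-second minimum-length validity rule holds).
makeRecording <- function(x, y, z, fs = length(x)) {
  new("TriaxialRecording", time = (seq_along(x) - 1) / fs,
      x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
      fs = as.numeric(fs))
}

makeEnmo <- function(values, fs, truncated = TRUE) {
  new("EnmoSeries", values = as.numeric(values), fs = as.numeric(fs),
      truncated = truncated)
}

# Tiny configuration for gradient checks: small enough that a full
# finite-difference sweep is cheap.
gradcheckModel <- function(seed = 3L) {
  vitBilstm(imageSize = 8L, patchSize = 4L, embedDim = 8L, depth = 1L,
            heads = 2L, mlpRatio = 2L, hiddenSize = 3L, numLayers = 2L,
            seqLen = 2L, dropout = 0, seed = seed)
}

# A small labelled dataset at reduced resolution for split / IO tests.
smallDataset <- function(nPerClass = 5L, resolution = 16L, seed = 1L) {
  simulateIntensityDataset(nPerClass = nPerClass, twS = 1L, noiseSd = 0.01,
                           seqLen = 4L, resolution = resolution, seed = seed)
}

# Random balanced accuracy table for ANOVA tests.
randomAccuracyTable <- function(tws = c(1, 5, 10, 15, 30),
                                pais = c("SD", "LPA", "MVPA"),
                                nRep = 3L, effect = 0) {
  grid <- expand.grid(tw = tws, pai = pais, replicate = seq_len(nRep),
                      stringsAsFactors = FALSE)
  grid$accuracy <- 0.95 + effect * as.integer(factor(grid$pai)) / 100 +
    rnorm(nrow(grid), 0, 0.01)
  grid
}

# Definitional two-way ANOVA oracle written independently of the package:
# plain loops over factor levels.
anovaOracle <- function(tab) {
  A <- as.character(tab$tw); B <- as.character(tab$pai); y <- tab$accuracy
  la <- unique(A); lb <- unique(B)
  a <- length(la); b <- length(lb)
  n <- sum(A == la[1] & B == lb[1])
  grand <- mean(y)
  ssA <- 0
  for (ai in la) ssA <- ssA + b * n * (mean(y[A == ai]) - grand)^2
  ssB <- 0
  for (bi in lb) ssB <- ssB + a * n * (mean(y[B == bi]) - grand)^2
  ssAB <- 0; ssW <- 0
  for (ai in la) for (bi in lb) {
    cell <- y[A == ai & B == bi]
    cm <- mean(cell)
    ssAB <- ssAB + n * (cm - mean(y[A == ai]) - mean(y[B == bi]) + grand)^2
    ssW <- ssW + sum((cell - cm)^2)
  }
  dfA <- a - 1; dfB <- b - 1; dfAB <- dfA * dfB; dfW <- a * b * (n - 1)
  msW <- ssW / dfW
  list(ssA = ssA, ssB = ssB, ssAB = ssAB, ssW = ssW,
       fA = (ssA / dfA) / msW, fB = (ssB / dfB) / msW,
       pA = pf((ssA / dfA) / msW, dfA, dfW, lower.tail = FALSE),
       pB = pf((ssB / dfB) / msW, dfB, dfW, lower.tail = FALSE))
}

# Random confusion matrix with every class present in the truth.
randomConfusion <- function(k = 3L) {
  m <- matrix(rpois(k * k, 5), k, k)
  diag(m) <- diag(m) + 1          # ensure nonzero rows
  m
}
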