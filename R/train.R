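# Training: stratified splitting, Adam with step learning-rate decay,
# cross-entropy minibatch loop with per-epoch accuracy/loss curves.

#' Training configuration
#'
#' Defaults follow the reference training recipe: batch size 16, 10
#' epochs, Adam (beta1 0.9, beta2 0.999) at learning rate 1e-5 with weight
#' decay 0.001, a step scheduler multiplying the rate by 0.8 every epoch,
#' dropout 0.5, and a stratified 60/20/20 train/validation/test split.
#'
#' @param batchSize minibatch size.
#' @param epochs training epochs (no early stopping).
#' @param lr initial learning rate.
#' @param weightDecay L2 penalty coefficient added to the gradients.
#' @param beta1,beta2 Adam moment decay rates.
#' @param schedulerGamma per-epoch multiplicative learning-rate factor.
#' @param dropout dropout probability before the output layer.
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer seed controlling shuffling and dropout.
#' @return named list of training settings.
#' @export
trainConfig <- function(batchSize = 16L, epochs = 10L, lr = 1e-5,
                        weightDecay = 0.001, beta1 = 0.9, beta2 = 0.999,
                        schedulerGamma = 0.8, dropout = 0.5,
                        fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(epochs >= 1L, abs(sum(fractions) - 1) < 1e-9,
            length(fractions) == 3L)
  list(batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       lr = lr, weightDecay = weightDecay, beta1 = beta1, beta2 = beta2,
       schedulerGamma = schedulerGamma, dropout = dropout,
       fractions = fractions, seed = as.integer(seed))
}

#' Effective learning rate at a given epoch
#'
#' Step scheduler with step size 1: `lr * gamma^(epoch - 1)`.
#'
#' @param cfg a [trainConfig()] list.
#' @param epoch 1-based epoch index.
#' @return numeric learning rate.
#' @export
scheduledLr <- function(cfg, epoch) cfg$lr * cfg$schedulerGamma^(epoch - 1)

# take a subset of a SequenceSet
subsetSequences <- function(sequences, idx) {
  new("SequenceSet",
      images = sequences@images[idx, , , , drop = FALSE],
      labels = factor(as.character(sequences@labels[idx]),
                      levels = intensityLevels()),
      twS = sequences@twS, resolution = sequences@resolution)
}

#' Stratified train/validation/test split
#'
#' Shuffles within each class under the seed, then allocates the class's
#' members to the three partitions by largest-remainder rounding of the
#' fractions, so the partitions are disjoint, exhaustive, and
#' approximately stratified. A class with fewer than 3 members is kept
#' whole in the training partition with a warning.
#'
#' @param sequences a [SequenceSet-class] with at least 5 sequences.
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer seed; identical seeds give identical partitions.
#' @return named list of three [SequenceSet-class] objects
#'   (`train`, `val`, `test`).
#' @export
splitDataset <- function(sequences, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(is(sequences, "SequenceSet"))
  n <- nObs(sequences)
  if (n < 5L) stop("need at least 5 sequences to split")
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  labs <- sequences@labels
  parts <- list(train = integer(0), val = integer(0), test = integer(0))
  withSeed(seed, {
    for (cl in levels(labs)) {
      idx <- which(labs == cl)
      if (length(idx) == 0L) next
      if (length(idx) < 3L) {
        warning(sprintf("class %s has %d member(s); keeping it whole in train",
                        cl, length(idx)))
        parts$train <- c(parts$train, idx)
        next
      }
      idx <- idx[sample.int(length(idx))]
      sizes <- largestRemainder(length(idx), fractions)
      parts$train <- c(parts$train, idx[seq_len(sizes[1])])
      parts$val <- c(parts$val, idx[sizes[1] + seq_len(sizes[2])])
      parts$test <- c(parts$test, idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
    }
  })
  lapply(parts, function(ix) subsetSequences(sequences, sort(ix)))
}

# integer allocation of n into parts proportional to fractions
largestRemainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order <- order(raw - base, decreasing = TRUE)
    base[order[seq_len(rem)]] <- base[order[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Adam update; state holds first/second moments and the step counter.
adamStep <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] + cfg$weightDecay * params[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
  }
  list(params = params, state = state)
}

# loss and accuracy of a model on a SequenceSet (evaluation mode)
evalLossAcc <- function(model, sequences) {
  res <- classify(model, sequences)
  y <- as.integer(sequences@labels)
  list(loss = crossEntropy(res$prob, y),
       acc = mean(res$label == sequences@labels))
}

#' Train a ViT-BiLSTM classifier
#'
#' Minibatch Adam on the cross-entropy loss
#' `L(y, yhat) = -sum_i y_i log(yhat_i)`, with the learning rate
#' multiplied by `schedulerGamma` after every epoch and inverted dropout
#' on the BiLSTM output during training. Deterministic for a fixed seed.
#'
#' @param model a freshly constructed [ViTBiLSTM-class].
#' @param train,val [SequenceSet-class] training and validation sets.
#' @param cfg a [trainConfig()] list.
#' @param verbose print a line per epoch.
#' @return a [TrainResult-class] with per-epoch curves.
#' @export
trainModel <- function(model, train, val, cfg = trainConfig(),
                       verbose = FALSE) {
  stopifnot(is(model, "ViTBiLSTM"), nObs(train) > 0L, nObs(val) > 0L)
  t0 <- proc.time()[["elapsed"]]
  nTrain <- nObs(train)
  yTrain <- as.integer(train@labels)
  state <- list(t = 0L,
                m = lapply(model@params, function(p) p * 0),
                v = lapply(model@params, function(p) p * 0))
  curves <- data.frame(epoch = integer(0), lr = numeric(0),
                       trainLoss = numeric(0), trainAcc = numeric(0),
                       valLoss = numeric(0), valAcc = numeric(0))
  withSeed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- scheduledLr(cfg, epoch)
      ord <- sample.int(nTrain)
      epochLoss <- 0
      epochCorrect <- 0
      for (s in seq(1L, nTrain, by = cfg$batchSize)) {
        idx <- ord[s:min(s + cfg$batchSize - 1L, nTrain)]
        images <- train@images[idx, , , , drop = FALSE]
        y <- yTrain[idx]
        dropMask <- if (cfg$dropout > 0) {
          matrix((runif(length(idx) * 2 * model@config$hiddenSize) >=
                    cfg$dropout) / (1 - cfg$dropout),
                 length(idx), 2 * model@config$hiddenSize)
        } else NULL
        fw <- nnForward(model, images, dropMask = dropMask, keepCache = TRUE)
        loss <- crossEntropy(fw$prob, y)
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d; aborting training", epoch))
        }
        epochLoss <- epochLoss + loss * length(idx)
        epochCorrect <- epochCorrect + sum(max.col(fw$prob, "first") == y)
        if (lr > 0) {
          grads <- nnBackward(model, fw$cache, crossEntropyGrad(fw$prob, y))
          upd <- adamStep(model@params, grads, state, lr, cfg)
          model@params <- upd$params
          state <- upd$state
        }
      }
      ev <- evalLossAcc(model, val)
      curves <- rbind(curves, data.frame(
        epoch = epoch, lr = lr,
        trainLoss = epochLoss / nTrain, trainAcc = epochCorrect / nTrain,
        valLoss = ev$loss, valAcc = ev$acc))
      if (verbose) {
        message(sprintf(
          "epoch %2d lr %.2e | train loss %.4f acc %.4f | val loss %.4f acc %.4f",
          epoch, lr, epochLoss / nTrain, epochCorrect / nTrain, ev$loss, ev$acc))
      }
    }
  })
  new("TrainResult", model = model, curves = curves,
      wallTime = proc.time()[["elapsed"]] - t0)
}

#' Write training curves as CSV
#'
#' Columns `epoch,train_acc,val_acc,train_loss,val_loss`.
#'
#' @param result a [TrainResult-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCurves <- function(result, path) {
  cv <- trainingCurves(result)
  utils::write.csv(
    data.frame(epoch = cv$epoch, train_acc = cv$trainAcc,
               val_acc = cv$valAcc, train_loss = cv$trainLoss,
               val_loss = cv$valLoss),
    path, row.names = FALSE)
  invisible(path)
}
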