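#' @describeIn nObs number of windows
#' @export
setMethod("nObs", "WindowSet", function(object) nrow(object@samples))

#' @describeIn nObs number of sequences
#' @export
setMethod("nObs", "SequenceSet", function(object) dim(object@images)[1])

#' @describeIn classLabels window labels
#' @export
setMethod("classLabels", "WindowSet", function(object) object@labels)

#' @describeIn classLabels sequence labels
#' @export
setMethod("classLabels", "SequenceSet", function(object) object@labels)

#' @describeIn classLabels label of a single image
#' @export
setMethod("classLabels", "GafImage", function(object) object@label)

setMethod("show", "ActivityScript", function(object) {
  cat(sprintf("ActivityScript: %d segment(s), %d s total, noiseSd=%g g, seed=%d\n",
              length(object@durations), sum(object@durations), object@noiseSd,
              object@seed))
  cat("  per-second ENMO targets (g*s):",
      paste(sprintf("%gs@%g", object@durations, object@targets), collapse = ", "),
      "\n")
})

setMethod("show", "TriaxialRecording", function(object) {
  cat(sprintf("TriaxialRecording: %d samples @ %g Hz (%.1f s)\n",
              length(object@x), object@fs, length(object@x) / object@fs))
})

setMethod("show", "EnmoSeries", function(object) {
  cat(sprintf("EnmoSeries: %d samples @ %g Hz, %s, range [%.4g, %.4g] g\n",
              length(object@values), object@fs,
              if (object@truncated) "truncated at 0" else "signed",
              min(object@values), max(object@values)))
})

setMethod("show", "IntensityThresholds", function(object) {
  cat(sprintf("IntensityThresholds (g*s per second): SD [0, %g) | LPA [%g, %g] | MVPA (%g, Inf)\n",
              object@sdUpper, object@sdUpper, object@lpaUpper, object@lpaUpper))
})

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet: %d window(s) of %g s @ %g Hz\n",
              nObs(object), object@twS, object@fs))
  if (nObs(object) > 0) print(table(object@labels))
})

setMethod("show", "GafImage", function(object) {
  cat(sprintf("GafImage: %dx%dx3, label=%s, tw=%g s, start=%g s\n",
              dim(object@pixels)[1], dim(object@pixels)[2],
              object@label, object@twS, object@startTime))
})

setMethod("show", "SequenceSet", function(object) {
  d <- dim(object@images)
  cat(sprintf("SequenceSet: %d sequence(s) of %d image(s), %dx%d px, tw=%g s\n",
              d[1], d[2], d[3], d[4], object@twS))
  if (d[1] > 0) print(table(object@labels))
})

setMethod("show", "ViTBiLSTM", function(object) {
  cfg <- object@config
  cat("ViTBiLSTM classifier\n")
  cat(sprintf("  ViT: image %dpx / patch %dpx -> %d patches + cls, dim %d, depth %d, heads %d\n",
              cfg$imageSize, cfg$patchSize,
              (cfg$imageSize / cfg$patchSize)^2, cfg$embedDim, cfg$depth,
              cfg$heads))
  cat(sprintf("  BiLSTM: hidden %d x %d layer(s), bidirectional -> %d features\n",
              cfg$hiddenSize, cfg$numLayers, 2 * cfg$hiddenSize))
  cat(sprintf("  Head: dropout %g -> %d classes (%s)\n",
              cfg$dropout, length(object@classes),
              paste(object@classes, collapse = ", ")))
  nPar <- sum(rapply(object@params, length, how = "unlist"))
  cat(sprintf("  Parameters: %s\n", format(nPar, big.mark = ",")))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: accuracy %.4f, macro F1 %.4f\n",
              object@accuracy, object@macroF1))
  cat("Confusion (rows = truth, cols = predicted):\n")
  print(object@confusion)
  print(object@perClass, digits = 4)
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("Two-way ANOVA (balanced, alpha = %g)\n", object@alpha))
  print(object@table, digits = 5)
})

setMethod("show", "TrainResult", function(object) {
  n <- nrow(object@curves)
  cat(sprintf("TrainResult: %d epoch(s), %.1f s\n", n, object@wallTime))
  if (n > 0) {
    last <- object@curves[n, ]
    cat(sprintf("  final: train acc %.4f / loss %.4f, val acc %.4f / loss %.4f\n",
                last$trainAcc, last$trainLoss, last$valAcc, last$valLoss))
  }
})

#' Training curves of a fitted model
#' @param result a [TrainResult-class].
#' @return data.frame of per-epoch curves.
#' @export
trainingCurves <- function(result) {
  stopifnot(is(result, "TrainResult"))
  result@curves
}

#' Fitted model of a training run
#' @param result a [TrainResult-class].
#' @return the trained [ViTBiLSTM-class].
#' @export
fittedModel <- function(result) {
  stopifnot(is(result, "TrainResult"))
  result@model
}

#' Confusion matrix of an evaluation
#' @param report a [MetricsReport-class].
#' @return 3x3 count matrix (rows = truth).
#' @export
confusionMatrix <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  report@confusion
}

#' Per-class metric table of an evaluation
#' @param report a [MetricsReport-class].
#' @return data.frame with recall, one-vs-rest accuracy, precision, F1, AUC.
#' @export
perClassMetrics <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  report@perClass
}

#' Overall accuracy of an evaluation
#' @param report a [MetricsReport-class].
#' @return proportion in `[0, 1]`.
#' @export
overallAccuracy <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  report@accuracy
}

#' ANOVA table
#' @param result an [AnovaResult-class].
#' @return data.frame with columns term, ss, df, ms, F, p.
#' @export
anovaTable <- function(result) {
  stopifnot(is(result, "AnovaResult"))
  result@table
}
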