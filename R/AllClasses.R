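#' @import methods
#' @importFrom stats rnorm runif pf pnorm dnorm sd
NULL

#' ActivityScript: a scripted intensity profile for the signal simulator
#'
#' An `ActivityScript` describes a synthetic wear episode as an ordered set
#' of constant-intensity segments. Each segment has an integer duration in
#' seconds and a target per-second cumulative ENMO sum (units g*s per
#' second, the same scale as the intensity cut-points), so windows cut from
#' the simulated recording land in known intensity classes by construction.
#'
#' @slot durations integer vector, segment durations in whole seconds.
#' @slot targets numeric vector, per-second cumulative ENMO target of each
#'   segment (g*s per second, >= 0).
#' @slot gravity unit 3-vector giving the constant gravity orientation of
#'   the simulated device (g).
#' @slot noiseSd standard deviation of additive per-axis Gaussian sensor
#'   noise (g).
#' @slot seed integer seed for the simulator's random draws.
#'
#' @seealso [activityScript()], [generateRecording()]
#' @exportClass ActivityScript
setClass("ActivityScript",
  slots = c(
    durations = "integer",
    targets = "numeric",
    gravity = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("ActivityScript", function(object) {
  msg <- character()
  if (length(object@durations) != length(object@targets)) {
    msg <- c(msg, "durations and targets must have equal length")
  }
  if (length(object@durations) < 1L) msg <- c(msg, "need at least one segment")
  if (any(object@durations < 1L)) {
    msg <- c(msg, "every segment duration must be a positive whole number of seconds")
  }
  if (any(object@targets < 0)) msg <- c(msg, "segment targets must be >= 0")
  if (length(object@gravity) != 3L) msg <- c(msg, "gravity must be a 3-vector")
  nrm <- sqrt(sum(object@gravity^2))
  if (abs(nrm - 1) > 1e-9) {
    msg <- c(msg, sprintf("gravity orientation must be a unit vector (norm %.12f)", nrm))
  }
  if (length(object@noiseSd) != 1L || object@noiseSd < 0) {
    msg <- c(msg, "noiseSd must be a single value >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' TriaxialRecording: uniformly sampled triaxial acceleration
#'
#' Time-indexed x/y/z acceleration in units of g at a fixed sampling rate.
#' This is the simulator's output and the processing pipeline's input; real
#' recordings can be read from CSV with [readRecording()].
#'
#' @slot time sample times in seconds (uniform grid, step 1/fs).
#' @slot x,y,z per-axis acceleration in g.
#' @slot fs sampling frequency in Hz.
#'
#' @seealso [computeEnmo()], [readRecording()], [writeRecording()]
#' @exportClass TriaxialRecording
setClass("TriaxialRecording",
  slots = c(time = "numeric", x = "numeric", y = "numeric", z = "numeric",
            fs = "numeric")
)

setValidity("TriaxialRecording", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@x) != n || length(object@y) != n || length(object@z) != n) {
    msg <- c(msg, "time, x, y, z must have equal length")
  }
  if (length(object@fs) != 1L || object@fs <= 0 ||
      abs(object@fs - round(object@fs)) > 1e-9) {
    msg <- c(msg, "fs must be a single positive integer (Hz)")
  }
  if (n < object@fs) {
    msg <- c(msg, "recording must contain at least one full second of samples")
  }
  if (n >= 2L) {
    step <- diff(object@time)
    if (any(abs(step - 1 / object@fs) > 1e-9)) {
      msg <- c(msg, "time must be a uniform grid with step 1/fs")
    }
  }
  if (length(msg)) msg else TRUE
})

#' EnmoSeries: per-sample Euclidean Norm Minus One signal
#'
#' The gravity-removed movement magnitude sqrt(x^2+y^2+z^2) - 1, in g, at
#' the source recording's sampling rate. When `truncated` is TRUE negative
#' values have been replaced by zero (the convention used before image
#' encoding).
#'
#' @slot values per-sample ENMO in g.
#' @slot fs sampling frequency in Hz.
#' @slot truncated logical; TRUE if negative values were zeroed.
#'
#' @seealso [computeEnmo()], [perSecondSums()], [segmentWindows()]
#' @exportClass EnmoSeries
setClass("EnmoSeries",
  slots = c(values = "numeric", fs = "numeric", truncated = "logical")
)

setValidity("EnmoSeries", function(object) {
  msg <- character()
  if (length(object@values) < 1L) msg <- c(msg, "values must be nonempty")
  if (length(object@fs) != 1L || object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (isTRUE(object@truncated) && any(object@values < 0)) {
    msg <- c(msg, "truncated series must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' IntensityThresholds: cumulative-acceleration cut-points
#'
#' Cut-points on the mean per-second cumulative ENMO sum (g*s per second)
#' separating sedentary (SD), light (LPA) and moderate-to-vigorous (MVPA)
#' activity. Defaults follow the Hildebrand adult wrist cut-points on the
#' gravity scale: SD `[0, 10)`, LPA `[10, 42]`, MVPA `(42, Inf)`.
#'
#' @slot sdUpper upper bound of the sedentary band (g*s per second).
#' @slot lpaUpper upper bound of the light band (g*s per second).
#'
#' @seealso [intensityThresholds()], [windowLabel()]
#' @exportClass IntensityThresholds
setClass("IntensityThresholds",
  slots = c(sdUpper = "numeric", lpaUpper = "numeric")
)

setValidity("IntensityThresholds", function(object) {
  if (length(object@sdUpper) != 1L || length(object@lpaUpper) != 1L) {
    return("sdUpper and lpaUpper must be single values")
  }
  if (!(object@sdUpper > 0 && object@lpaUpper > object@sdUpper)) {
    return("need 0 < sdUpper < lpaUpper")
  }
  TRUE
})

#' WindowSet: labelled fixed-length ENMO windows
#'
#' A vectorised container of consecutive non-overlapping temporal windows
#' cut from one ENMO series. Row `i` of `samples` holds the `twS * fs`
#' ENMO values of window `i`; `perSecondSums` holds its `twS` per-second
#' cumulative sums; `labels` holds the SD/LPA/MVPA class assigned from the
#' mean per-second sum.
#'
#' @slot samples numeric matrix, one window per row (`twS * fs` columns).
#' @slot perSecondSums numeric matrix, one window per row (`twS` columns),
#'   units g*s.
#' @slot labels factor with levels SD, LPA, MVPA.
#' @slot startTime numeric vector, window start times in seconds.
#' @slot twS temporal window length in seconds.
#' @slot fs sampling frequency in Hz.
#' @slot thresholds the [IntensityThresholds-class] used for labelling.
#'
#' @seealso [segmentWindows()], [gafEncode()]
#' @exportClass WindowSet
setClass("WindowSet",
  slots = c(
    samples = "matrix",
    perSecondSums = "matrix",
    labels = "factor",
    startTime = "numeric",
    twS = "numeric",
    fs = "numeric",
    thresholds = "IntensityThresholds"
  )
)

setValidity("WindowSet", function(object) {
  msg <- character()
  n <- nrow(object@samples)
  if (ncol(object@samples) != object@twS * object@fs) {
    msg <- c(msg, "samples must have twS * fs columns")
  }
  if (nrow(object@perSecondSums) != n || ncol(object@perSecondSums) != object@twS) {
    msg <- c(msg, "perSecondSums must be n x twS")
  }
  if (length(object@labels) != n || length(object@startTime) != n) {
    msg <- c(msg, "labels and startTime must have one entry per window")
  }
  if (!identical(levels(object@labels), intensityLevels())) {
    msg <- c(msg, "labels must be a factor with levels SD, LPA, MVPA")
  }
  if (length(msg)) msg else TRUE
})

#' GafImage: a Gramian Angular Field raster
#'
#' A single temporal window encoded as a fixed-resolution 3-channel image:
#' the window's ENMO values are min-max normalised to `[-1, 1]`, mapped to
#' polar angles by arccos, expanded to the Gramian matrix
#' `G[i, j] = cos(theta_i + theta_j)`, affinely rescaled to `[0, 1]`,
#' resized by bilinear interpolation and quantised to 8-bit.
#'
#' @slot pixels integer-valued array `resolution x resolution x 3`, 0-255.
#' @slot label intensity class of the source window ("SD", "LPA", "MVPA",
#'   or NA if unlabelled).
#' @slot twS source temporal window length in seconds.
#' @slot startTime source window start time in seconds.
#'
#' @seealso [renderImage()], [gafEncode()], [writeGafPng()]
#' @exportClass GafImage
setClass("GafImage",
  slots = c(pixels = "array", label = "character", twS = "numeric",
            startTime = "numeric")
)

setValidity("GafImage", function(object) {
  d <- dim(object@pixels)
  msg <- character()
  if (length(d) != 3L || d[3] != 3L || d[1] != d[2]) {
    msg <- c(msg, "pixels must be a square H x H x 3 array")
  }
  if (any(object@pixels < 0) || any(object@pixels > 255) ||
      any(abs(object@pixels - round(object@pixels)) > 0)) {
    msg <- c(msg, "pixels must be integers in 0-255")
  }
  if (length(msg)) msg else TRUE
})

#' SequenceSet: ordered GAF-image sequences with one label each
#'
#' The classifier's unit of input: runs of `seqLen` consecutive window
#' images from one recording and one temporal window length, each run
#' carrying a single intensity label (majority label of its windows, ties
#' broken by the last window). Images are stored as a single grayscale
#' plane per window (the three raster channels are replicated grayscale);
#' the model expands channels at embedding time.
#'
#' @slot images numeric array `n x seqLen x H x H` of 0-255 pixel values.
#' @slot labels factor with levels SD, LPA, MVPA, one per sequence.
#' @slot twS temporal window length (seconds) of the source windows.
#' @slot resolution image side length in pixels.
#'
#' @seealso [buildSequences()], [simulateIntensityDataset()], [classify()]
#' @exportClass SequenceSet
setClass("SequenceSet",
  slots = c(images = "array", labels = "factor", twS = "numeric",
            resolution = "numeric")
)

setValidity("SequenceSet", function(object) {
  d <- dim(object@images)
  msg <- character()
  if (length(d) != 4L || d[3] != d[4]) {
    msg <- c(msg, "images must be an n x seqLen x H x H array")
  }
  if (length(object@labels) != d[1]) {
    msg <- c(msg, "one label per sequence required")
  }
  if (!identical(levels(object@labels), intensityLevels())) {
    msg <- c(msg, "labels must be a factor with levels SD, LPA, MVPA")
  }
  if (d[3] != object@resolution) {
    msg <- c(msg, "image side must equal resolution")
  }
  if (length(msg)) msg else TRUE
})

#' ViTBiLSTM: the hybrid image-sequence classifier
#'
#' A vision transformer encodes each Gramian Angular Field image of a
#' sequence into a feature vector (class-token representation after the
#' final encoder layer); a bidirectional LSTM reads the per-image feature
#' vectors forwards and backwards; the concatenated final hidden states
#' pass through a dropout + linear + softmax head over the three intensity
#' classes.
#'
#' @slot config named list of architecture hyperparameters (see
#'   [vitBilstm()]).
#' @slot params named list of weight matrices and vectors.
#' @slot classes character vector of class names, in output order.
#'
#' @seealso [vitBilstm()], [classify()], [trainModel()]
#' @exportClass ViTBiLSTM
setClass("ViTBiLSTM",
  slots = c(config = "list", params = "list", classes = "character")
)

#' MetricsReport: multiclass evaluation results
#'
#' Confusion matrix (rows = truth, columns = prediction) plus the derived
#' scalar metrics for one evaluation run. Per-class metrics for a class
#' absent from the truth are NA, never 0.
#'
#' @slot confusion 3x3 count matrix, rows truth / columns prediction.
#' @slot accuracy overall accuracy (diagonal sum / total).
#' @slot perClass data.frame with one row per class: recall (the usual
#'   reading of "per-class accuracy"), one-vs-rest accuracy, precision,
#'   F1, and one-vs-rest ROC AUC.
#' @slot macroF1 unweighted mean of the per-class F1 scores.
#' @slot kappa Cohen's kappa (NA unless requested).
#'
#' @seealso [evaluateModel()], [confusionMetrics()]
#' @exportClass MetricsReport
setClass("MetricsReport",
  slots = c(confusion = "matrix", accuracy = "numeric",
            perClass = "data.frame", macroF1 = "numeric", kappa = "numeric")
)

#' AnovaResult: balanced two-way fixed-effects ANOVA table
#'
#' Sums of squares, degrees of freedom, mean squares, F statistics and
#' p-values for the two factors (temporal window and intensity), their
#' interaction, the residual, and the total, computed by definitional sums
#' of squares on a balanced design.
#'
#' @slot table data.frame with columns term, ss, df, ms, F, p.
#' @slot alpha significance level echoed in the show method (0.05).
#'
#' @seealso [twoWayAnova()]
#' @exportClass AnovaResult
setClass("AnovaResult", slots = c(table = "data.frame", alpha = "numeric"))

#' TrainResult: training curves and the fitted model
#'
#' @slot model the trained [ViTBiLSTM-class].
#' @slot curves data.frame with one row per epoch: epoch, lr, trainLoss,
#'   trainAcc, valLoss, valAcc.
#' @slot wallTime elapsed training time in seconds (informational).
#'
#' @seealso [trainModel()]
#' @exportClass TrainResult
setClass("TrainResult",
  slots = c(model = "ViTBiLSTM", curves = "data.frame", wallTime = "numeric")
)

#' Intensity class levels
#'
#' The canonical ordering of the three physical-activity-intensity classes
#' used throughout the package: sedentary, light, moderate-to-vigorous.
#'
#' @return character vector `c("SD", "LPA", "MVPA")`.
#' @export
intensityLevels <- function() c("SD", "LPA", "MVPA")
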