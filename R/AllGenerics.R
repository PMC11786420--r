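#' Compute the Euclidean Norm Minus One signal
#'
#' @param rec a [TriaxialRecording-class].
#' @param truncate logical; replace negative values by zero (default TRUE,
#'   the convention used before image encoding).
#' @return an [EnmoSeries-class].
#' @export
setGeneric("computeEnmo", function(rec, truncate = TRUE)
  standardGeneric("computeEnmo"))

#' Segment an ENMO series into labelled temporal windows
#'
#' @param enmo an [EnmoSeries-class].
#' @param twS temporal window length in whole seconds (1, 5, 10, 15 and 30
#'   are the conventional choices).
#' @param thresholds an [IntensityThresholds-class].
#' @return a [WindowSet-class]; empty (zero rows, with a warning) when the
#'   series is shorter than one window.
#' @export
setGeneric("segmentWindows", function(enmo, twS,
                                      thresholds = intensityThresholds())
  standardGeneric("segmentWindows"))

#' Classify image sequences
#'
#' Runs the model in evaluation mode (dropout off) and returns class
#' probabilities and predicted labels.
#'
#' @param model a [ViTBiLSTM-class].
#' @param sequences a [SequenceSet-class] whose sequence length and image
#'   resolution match the model configuration.
#' @return list with `prob` (n x 3 matrix of softmax probabilities, rows
#'   summing to 1) and `label` (factor of predicted classes).
#' @export
setGeneric("classify", function(model, sequences) standardGeneric("classify"))

#' Number of observations in a container
#' @param object a WindowSet or SequenceSet.
#' @return integer count.
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))

#' Intensity labels stored in a container
#' @param object a WindowSet, SequenceSet or GafImage.
#' @return factor (or character for a single image).
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))
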