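# ENMO computation, per-second cumulative sums, and intensity labelling.

#' @describeIn computeEnmo per-sample `sqrt(x^2+y^2+z^2) - 1`, optionally
#'   truncated at zero.
#' @export
setMethod("computeEnmo", "TriaxialRecording", function(rec, truncate = TRUE) {
  validObject(rec)
  v <- sqrt(rec@x^2 + rec@y^2 + rec@z^2) - 1
  if (truncate) v <- pmax(v, 0)
  new("EnmoSeries", values = v, fs = rec@fs, truncated = isTRUE(truncate))
})

#' ENMO sample values
#' @param enmo an [EnmoSeries-class].
#' @return numeric vector of per-sample ENMO in g.
#' @export
enmoValues <- function(enmo) {
  stopifnot(is(enmo, "EnmoSeries"))
  enmo@values
}

#' Default intensity cut-points
#'
#' Cut-points on the mean per-second cumulative ENMO sum: sedentary below
#' `sdUpper`, light between `sdUpper` and `lpaUpper` inclusive,
#' moderate-to-vigorous strictly above `lpaUpper`.
#'
#' @param sdUpper sedentary/light cut-point (default 10 g*s per second).
#' @param lpaUpper light/MVPA cut-point (default 42 g*s per second).
#' @return an [IntensityThresholds-class].
#' @export
intensityThresholds <- function(sdUpper = 10, lpaUpper = 42) {
  new("IntensityThresholds", sdUpper = as.numeric(sdUpper),
      lpaUpper = as.numeric(lpaUpper))
}

#' Per-second cumulative ENMO sums
#'
#' Element `k` is the sum of ENMO over samples `[(k-1)*fs + 1, k*fs]`
#' (units g*s). A trailing partial second is dropped with a warning.
#'
#' @param enmo an [EnmoSeries-class] with at least `fs` samples.
#' @return numeric vector, one value per whole second.
#' @export
perSecondSums <- function(enmo) {
  stopifnot(is(enmo, "EnmoSeries"))
  fs <- as.integer(round(enmo@fs))
  n <- length(enmo@values)
  if (n < fs) stop("need at least one full second of samples")
  nSec <- n %/% fs
  if (n %% fs != 0L) {
    warning(sprintf("dropping trailing partial second (%d samples)", n %% fs))
  }
  colSums(matrix(enmo@values[seq_len(nSec * fs)], nrow = fs))
}

#' Label a window from its per-second cumulative sums
#'
#' Compares the mean of the per-second cumulative ENMO sums against the
#' cut-points: SD when the mean is below `sdUpper`, LPA from `sdUpper` up
#' to and including `lpaUpper`, MVPA strictly above `lpaUpper` (the MVPA
#' band is open at the cut-point because it is defined as "greater than").
#'
#' @param sums nonempty numeric vector of nonnegative per-second sums (g*s).
#' @param thresholds an [IntensityThresholds-class].
#' @return one of "SD", "LPA", "MVPA".
#' @examples
#' windowLabel(5)   # "SD"
#' windowLabel(42)  # "LPA"  (boundary belongs to the light band)
#' windowLabel(60)  # "MVPA"
#' @export
windowLabel <- function(sums, thresholds = intensityThresholds()) {
  stopifnot(is(thresholds, "IntensityThresholds"))
  if (length(sums) < 1L) stop("need at least one per-second sum")
  if (any(sums < 0)) stop("per-second sums must be nonnegative")
  m <- mean(sums)
  if (m < thresholds@sdUpper) "SD"
  else if (m <= thresholds@lpaUpper) "LPA"
  else "MVPA"
}

#' @describeIn segmentWindows cut consecutive non-overlapping windows of
#'   `twS * fs` samples, label each via [windowLabel()], drop the
#'   incomplete tail.
#' @export
setMethod("segmentWindows", "EnmoSeries", function(enmo, twS,
                                                   thresholds = intensityThresholds()) {
  if (length(twS) != 1L || twS < 1 || abs(twS - round(twS)) > 1e-9) {
    stop("twS must be a positive whole number of seconds")
  }
  twS <- as.integer(round(twS))
  fs <- as.integer(round(enmo@fs))
  wlen <- twS * fs
  n <- length(enmo@values)
  nWin <- n %/% wlen
  if (nWin == 0L) {
    warning("recording shorter than one window; returning an empty WindowSet")
    return(new("WindowSet",
               samples = matrix(numeric(0), 0, wlen),
               perSecondSums = matrix(numeric(0), 0, twS),
               labels = factor(character(0), levels = intensityLevels()),
               startTime = numeric(0), twS = as.numeric(twS),
               fs = as.numeric(fs), thresholds = thresholds))
  }
  v <- enmo@values[seq_len(nWin * wlen)]
  samples <- matrix(v, nrow = nWin, byrow = TRUE)
  secs <- colSums(matrix(v, nrow = fs))            # one sum per second
  pss <- matrix(secs, nrow = nWin, byrow = TRUE)   # nWin x twS
  labs <- vapply(seq_len(nWin),
                 function(i) windowLabel(pss[i, ], thresholds), character(1))
  new("WindowSet",
      samples = samples,
      perSecondSums = pss,
      labels = factor(labs, levels = intensityLevels()),
      startTime = (seq_len(nWin) - 1) * twS,
      twS = as.numeric(twS), fs = as.numeric(fs), thresholds = thresholds)
})

#' Write window labels as CSV
#'
#' One row per window: `start_time,tw_s,label,mean_per_second_sum`.
#'
#' @param windows a [WindowSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeWindowLabels <- function(windows, path) {
  stopifnot(is(windows, "WindowSet"))
  df <- data.frame(
    start_time = windows@startTime,
    tw_s = rep(windows@twS, nObs(windows)),
    label = as.character(windows@labels),
    mean_per_second_sum = rowMeans(windows@perSecondSums)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
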