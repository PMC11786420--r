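# Synthetic triaxial accelerometer signals with analytically known ENMO.
#
# The movement component is collinear with gravity, so each sample's vector
# magnitude is exactly 1 + m_t (g) and the noise-free ENMO recovers m_t in
# closed form. Per-second movement sums are calibrated exactly to the
# scripted targets; sensor noise is added afterwards.

#' Create an activity script
#'
#' @param durations integer vector of segment durations (whole seconds).
#' @param targets numeric vector of per-second cumulative ENMO targets
#'   (g*s per second, >= 0), one per segment. A target of 5 lands in the
#'   sedentary band, 20 in the light band, 60 in the MVPA band under the
#'   default cut-points.
#' @param gravity unit 3-vector, constant gravity orientation (default
#'   `c(0, 0, 1)`).
#' @param noiseSd per-axis Gaussian sensor noise SD in g (default 0).
#' @param seed integer seed for the simulator (default 1).
#' @return an [ActivityScript-class].
#' @examples
#' sc <- activityScript(durations = c(10, 10), targets = c(5, 60))
#' rec <- generateRecording(sc, fs = 100)
#' @export
activityScript <- function(durations, targets, gravity = c(0, 0, 1),
                           noiseSd = 0, seed = 1L) {
  if (any(abs(durations - round(durations)) > 1e-9)) {
    stop("segment durations must be whole seconds")
  }
  new("ActivityScript",
      durations = as.integer(round(durations)),
      targets = as.numeric(targets),
      gravity = as.numeric(gravity),
      noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

# Movement cadence (Hz) as a function of per-second intensity. Once the
# window is min-max normalised for image encoding the absolute amplitude is
# gone, so — as in real accelerometry, where higher intensities come with
# faster arm cadence — intensity is carried by the temporal structure:
# sedentary fidgeting ~1 Hz, light activity ~1.6 Hz, vigorous ~2.4 Hz under
# the default mapping 0.5 + 0.25 * sqrt(target).
movementCadence <- function(target) 0.5 + 0.25 * sqrt(target)

# Per-sample movement magnitudes for one segment: a rectified-sinusoid
# cadence envelope times a uniform texture, rescaled second by second so
# the per-second sum equals the target exactly.
segmentMovement <- function(target, durationS, fs, tStart) {
  n <- durationS * fs
  if (target == 0) return(numeric(n))
  tt <- tStart + (seq_len(n) - 1) / fs
  phase <- runif(1, 0, 2 * pi)
  env <- pmax(0, sin(2 * pi * movementCadence(target) * tt + phase))
  m <- env * runif(n, 0.5, 1.5)
  for (s in seq_len(durationS)) {
    idx <- ((s - 1) * fs + 1):(s * fs)
    tot <- sum(m[idx])
    if (tot > 0) {
      m[idx] <- m[idx] * (target / tot)
    } else {
      m[idx] <- target / fs  # flat fallback for an all-zero envelope second
    }
  }
  m
}

#' Generate a synthetic triaxial recording from an activity script
#'
#' Each sample's acceleration vector is
#' `gravity * (1 + m_t) + noise`, where `m_t >= 0` is a seeded per-sample
#' movement magnitude calibrated so that the sum of `m_t` over every second
#' equals that segment's target exactly before noise. Because movement is
#' collinear with gravity, [computeEnmo()] of a noise-free recording
#' recovers `m_t` to within 1e-9, giving the simulator a closed-form
#' oracle.
#'
#' @param script an [ActivityScript-class].
#' @param fs sampling frequency in Hz (positive integer, default 100).
#' @return a [TriaxialRecording-class] with `fs * sum(durations)` samples.
#' @examples
#' sc <- activityScript(1L, 5, noiseSd = 0)
#' rec <- generateRecording(sc, fs = 100)
#' sum(enmoValues(computeEnmo(rec)))  # 5, exactly
#' @export
generateRecording <- function(script, fs = 100L) {
  stopifnot(is(script, "ActivityScript"))
  validObject(script)
  if (length(fs) != 1L || fs <= 0 || abs(fs - round(fs)) > 1e-9) {
    stop("fs must be a positive integer (Hz)")
  }
  fs <- as.integer(round(fs))
  withSeed(script@seed, {
    m <- numeric(0)
    tStart <- 0
    for (k in seq_along(script@durations)) {
      m <- c(m, segmentMovement(script@targets[k], script@durations[k], fs,
                                tStart))
      tStart <- tStart + script@durations[k]
    }
    n <- length(m)
    acc <- outer(1 + m, script@gravity)  # n x 3, movement collinear with gravity
    if (script@noiseSd > 0) {
      acc <- acc + matrix(rnorm(3 * n, sd = script@noiseSd), n, 3)
    }
    new("TriaxialRecording",
        time = (seq_len(n) - 1) / fs,
        x = acc[, 1], y = acc[, 2], z = acc[, 3],
        fs = as.numeric(fs))
  })
}

#' Simulate a labelled GAF image-sequence dataset
#'
#' Runs the full simulate -> ENMO -> window -> GAF -> sequence pipeline for
#' a set of constant-intensity scripts, one per class, and returns the
#' pooled sequences. This is the desk-scale stand-in for a real annotated
#' free-living dataset.
#'
#' @param nPerClass number of sequences per intensity class.
#' @param targets per-second ENMO targets for the three classes
#'   (g*s per second); the defaults 5 / 20 / 60 sit well inside the
#'   SD / LPA / MVPA bands.
#' @param twS temporal window length in seconds.
#' @param fs sampling frequency in Hz.
#' @param noiseSd per-axis sensor noise SD in g.
#' @param seqLen images per sequence.
#' @param resolution image side in pixels.
#' @param seed integer seed.
#' @param thresholds an [IntensityThresholds-class].
#' @return a [SequenceSet-class] with `3 * nPerClass` sequences.
#' @export
simulateIntensityDataset <- function(nPerClass, targets = c(5, 20, 60),
                                     twS = 1L, fs = 100L, noiseSd = 0.01,
                                     seqLen = 4L, resolution = 64L,
                                     seed = 1L,
                                     thresholds = intensityThresholds()) {
  stopifnot(length(targets) == 3L, nPerClass >= 1L)
  imgs <- NULL
  labs <- factor(character(0), levels = intensityLevels())
  for (k in 1:3) {
    dur <- nPerClass * seqLen * twS
    sc <- activityScript(dur, targets[k], noiseSd = noiseSd,
                         seed = as.integer(seed + 7919L * k))
    rec <- generateRecording(sc, fs = fs)
    ws <- segmentWindows(computeEnmo(rec), twS, thresholds)
    sq <- buildSequences(ws, seqLen = seqLen, resolution = resolution)
    imgs <- if (is.null(imgs)) sq@images else abindSeq(imgs, sq@images)
    labs <- factor(c(as.character(labs), as.character(sq@labels)),
                   levels = intensityLevels())
  }
  new("SequenceSet", images = imgs, labels = labs, twS = as.numeric(twS),
      resolution = as.numeric(resolution))
}

# bind two n x S x H x H arrays along the first axis
abindSeq <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[-1], db[-1]))
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

#' Write / read a recording as CSV
#'
#' The on-disk format is a four-column CSV with header `time,x,y,z`
#' (seconds, g, g, g). `writeRecording` optionally writes a JSON sidecar
#' describing the generating script.
#'
#' @param rec a [TriaxialRecording-class].
#' @param path output CSV path.
#' @param script optional [ActivityScript-class] written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, script = NULL) {
  stopifnot(is(rec, "TriaxialRecording"))
  df <- data.frame(time = rec@time, x = rec@x, y = rec@y, z = rec@z)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(script)) {
    jsonlite::write_json(
      list(durations = script@durations, targets = script@targets,
           gravity = script@gravity, noiseSd = script@noiseSd,
           seed = script@seed),
      paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeRecording
#' @param fs sampling frequency in Hz; if NULL it is inferred from the time
#'   column.
#' @export
readRecording <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("recording CSV must have columns time,x,y,z")
  }
  if (is.null(fs)) {
    step <- stats::median(diff(df$time))
    fs <- round(1 / step)
  }
  new("TriaxialRecording", time = df$time, x = df$x, y = df$y, z = df$z,
      fs = as.numeric(fs))
}

#' Read an activity script from JSON
#' @param path path to a script JSON (fields durations, targets, gravity,
#'   noiseSd, seed).
#' @return an [ActivityScript-class].
#' @export
readActivityScript <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  activityScript(durations = j$durations, targets = j$targets,
                 gravity = if (is.null(j$gravity)) c(0, 0, 1) else j$gravity,
                 noiseSd = if (is.null(j$noiseSd)) 0 else j$noiseSd,
                 seed = if (is.null(j$seed)) 1L else j$seed)
}
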