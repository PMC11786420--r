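# Gramian Angular Field encoding of ENMO windows.
#
# window values -> min-max normalise to [-1, 1] -> polar angles arccos ->
# G[i, j] = cos(theta_i + theta_j) -> affine rescale to [0, 1] -> bilinear
# resize -> 8-bit 3-channel raster.

#' Min-max normalise a window to `[-1, 1]`
#'
#' `v~ = (v - min) / (max - min) * 2 - 1`. A constant window (range below
#' `eps`) is degenerate for this map; all its values are set to -1 with a
#' warning.
#'
#' @param v nonempty numeric vector (one window of ENMO samples).
#' @param eps degeneracy tolerance on the range (default 1e-12).
#' @return numeric vector in `[-1, 1]`, same length as `v`.
#' @export
minmaxNormalize <- function(v, eps = 1e-12) {
  if (length(v) < 1L) stop("cannot normalise an empty window")
  rng <- max(v) - min(v)
  if (rng < eps) {
    warning("constant window: normalised values set to -1")
    return(rep(-1, length(v)))
  }
  (v - min(v)) / rng * 2 - 1
}

#' Map a normalised series to polar coordinates
#'
#' Angles are `theta_t = arccos(v~_t)` in `[0, pi]`; radii are the
#' normalised time index `r_t = t / T` (1-based). The radii preserve the
#' sequential ordering but do not enter the Gramian matrix.
#'
#' @param vtilde numeric vector with values in `[-1, 1]` (values beyond
#'   the bounds by at most `tol` are clipped; larger excursions error).
#' @param tol clipping tolerance (default 1e-9).
#' @return list with `theta` (radians) and `r` (dimensionless).
#' @export
toPolar <- function(vtilde, tol = 1e-9) {
  if (length(vtilde) < 1L) stop("empty series")
  if (any(vtilde < -1 - tol) || any(vtilde > 1 + tol)) {
    stop("normalised values must lie in [-1, 1]")
  }
  vt <- pmin(pmax(vtilde, -1), 1)
  list(theta = acos(vt), r = seq_along(vt) / length(vt))
}

#' Gramian Angular Field matrix
#'
#' `G[i, j] = cos(theta_i + theta_j)`, the pairwise cosine of summed polar
#' angles. G is symmetric with diagonal `2 * v~_i^2 - 1` and all entries
#' in `[-1, 1]`.
#'
#' @param polar list with component `theta` as returned by [toPolar()].
#' @return T x T numeric matrix.
#' @export
gafMatrix <- function(polar) {
  theta <- polar$theta
  if (length(theta) < 1L) stop("empty angle series")
  cos(outer(theta, theta, `+`))
}

#' Rescale a Gramian matrix to `[0, 1]`
#'
#' The fixed affine map `(g + 1) / 2`. It is intentionally not a per-image
#' min-max: the Gramian construction already guarantees `[-1, 1]`, and a
#' per-image rescale would destroy comparability across images.
#'
#' @param G matrix with entries in `[-1, 1]`.
#' @return matrix with entries in `[0, 1]`.
#' @export
rescale01 <- function(G) (G + 1) / 2

# Bilinear resize of a square matrix to res x res, pixel-centre aligned:
# output pixel i samples the input at (i - 0.5) * T / res - 0.5 (0-based),
# clamped at the borders.
bilinearResize <- function(M, res) {
  T <- nrow(M)
  if (res == T) return(M)
  xs <- (seq_len(res) - 0.5) * T / res - 0.5   # 0-based source coordinates
  xs <- pmin(pmax(xs, 0), T - 1)               # replicate edges beyond borders
  x0 <- floor(xs)
  x1 <- pmin(x0 + 1, T - 1)
  w <- xs - x0
  i0 <- as.integer(x0) + 1L; i1 <- as.integer(x1) + 1L
  A <- M[i0, i0, drop = FALSE] * outer(1 - w, 1 - w) +
       M[i0, i1, drop = FALSE] * outer(1 - w, w) +
       M[i1, i0, drop = FALSE] * outer(w, 1 - w) +
       M[i1, i1, drop = FALSE] * outer(w, w)
  A
}

#' Render a `[0, 1]` Gramian matrix as a raster image
#'
#' Resizes to `resolution x resolution` by bilinear interpolation,
#' quantises to 8 bits (`round(255 * value)`, round-half-up), and expands
#' to three channels. The default channel mode replicates the grayscale
#' plane; `"viridis"`-style colouring is deliberately not built in — any
#' colormap is a presentation choice, not part of the encoding.
#'
#' @param G01 square matrix with entries in `[0, 1]`.
#' @param resolution output side length in pixels (default 224).
#' @param channelMode `"replicate"` (grayscale copied to all 3 channels).
#' @param label,twS,startTime metadata carried on the image.
#' @return a [GafImage-class].
#' @export
renderImage <- function(G01, resolution = 224L, channelMode = "replicate",
                        label = NA_character_, twS = NA_real_,
                        startTime = NA_real_) {
  if (!is.matrix(G01) || nrow(G01) != ncol(G01)) stop("G01 must be square")
  if (resolution < 2) stop("resolution must be at least 2 pixels")
  if (any(G01 < -1e-12) || any(G01 > 1 + 1e-12)) {
    stop("G01 entries must lie in [0, 1]")
  }
  channelMode <- match.arg(channelMode, "replicate")
  plane <- gafPlane(G01, resolution)
  px <- array(0, dim = c(resolution, resolution, 3))
  for (c in 1:3) px[, , c] <- plane
  new("GafImage", pixels = px, label = as.character(label),
      twS = as.numeric(twS), startTime = as.numeric(startTime))
}

# resize + quantise, returning the 0-255 grayscale plane
gafPlane <- function(G01, resolution) {
  A <- bilinearResize(G01, as.integer(resolution))
  floor(255 * pmin(pmax(A, 0), 1) + 0.5)  # round half up
}

# one window vector -> quantised grayscale plane (suppressing the
# constant-window warning is the caller's business)
windowToPlane <- function(v, resolution) {
  vt <- minmaxNormalize(v)
  gafPlane(rescale01(gafMatrix(toPolar(vt))), resolution)
}

#' Encode every window of a WindowSet as a GAF image
#'
#' @param windows a [WindowSet-class].
#' @param resolution image side length in pixels.
#' @return list of [GafImage-class] objects, in window order.
#' @export
gafEncode <- function(windows, resolution = 224L) {
  stopifnot(is(windows, "WindowSet"))
  lapply(seq_len(nObs(windows)), function(i) {
    vt <- minmaxNormalize(windows@samples[i, ])
    renderImage(rescale01(gafMatrix(toPolar(vt))), resolution,
                label = as.character(windows@labels[i]),
                twS = windows@twS, startTime = windows@startTime[i])
  })
}

#' Group consecutive windows into classifier input sequences
#'
#' Non-overlapping runs of `seqLen` consecutive windows are encoded as GAF
#' images and stacked into a [SequenceSet-class]. Each run's label is the
#' majority label of its windows, ties broken in favour of the last window.
#' A trailing incomplete run is dropped.
#'
#' @param windows a [WindowSet-class].
#' @param seqLen images per sequence (default 4).
#' @param resolution image side length in pixels.
#' @return a [SequenceSet-class].
#' @export
buildSequences <- function(windows, seqLen = 4L, resolution = 224L) {
  stopifnot(is(windows, "WindowSet"), seqLen >= 1L)
  nWin <- nObs(windows)
  nSeq <- nWin %/% seqLen
  res <- as.integer(resolution)
  imgs <- array(0, dim = c(nSeq, seqLen, res, res))
  labs <- character(nSeq)
  for (s in seq_len(nSeq)) {
    idx <- ((s - 1) * seqLen + 1):(s * seqLen)
    for (j in seq_along(idx)) {
      imgs[s, j, , ] <- windowToPlane(windows@samples[idx[j], ], res)
    }
    labs[s] <- majorityLabel(as.character(windows@labels[idx]))
  }
  new("SequenceSet", images = imgs,
      labels = factor(labs, levels = intensityLevels()),
      twS = windows@twS, resolution = as.numeric(res))
}

# Majority vote; a tie goes to the most recent window whose label is among
# the tied leaders.
majorityLabel <- function(labs) {
  tab <- table(labs)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  for (j in rev(seq_along(labs))) if (labs[j] %in% top) return(labs[j])
  top[1]
}

#' Write a GAF image as PNG
#'
#' @param image a [GafImage-class].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeGafPng <- function(image, path) {
  stopifnot(is(image, "GafImage"))
  png::writePNG(image@pixels / 255, path)
  invisible(path)
}

#' Encode windows to a class-labelled PNG directory tree
#'
#' Writes `<out>/<tw>s/<label>/<start_time>.png` for every window plus an
#' `index.csv` (`path,label,tw_s,start_time`).
#'
#' @param windows a [WindowSet-class].
#' @param out output directory (created if needed).
#' @param resolution image side length in pixels.
#' @return data.frame index, invisibly.
#' @export
writeGafTree <- function(windows, out, resolution = 224L) {
  stopifnot(is(windows, "WindowSet"))
  imgs <- gafEncode(windows, resolution)
  rows <- lapply(imgs, function(im) {
    dir <- file.path(out, sprintf("%gs", im@twS), im@label)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(dir, sprintf("%g.png", im@startTime))
    writeGafPng(im, p)
    data.frame(path = p, label = im@label, tw_s = im@twS,
               start_time = im@startTime)
  })
  index <- do.call(rbind, rows)
  utils::write.csv(index, file.path(out, "index.csv"), row.names = FALSE)
  invisible(index)
}
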