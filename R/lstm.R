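# Bidirectional multi-layer LSTM over per-image feature vectors, with
# backpropagation through time. Gate layout in the 4H-wide weight blocks
# is (input, forget, cell, output).
#
#   h_t^forward  = LSTM(h_{t-1}^forward,  x_t, c_{t-1}^forward)
#   h_t^backward = LSTM(h_{t-1}^backward, x_t, c_{t-1}^backward)
#   h_final = [h_T^forward ; h_T^backward]   (final state of each direction)

lstmInitParams <- function(cfg) {
  H <- cfg$hiddenSize
  k <- 1 / sqrt(H)
  p <- list()
  inDim <- cfg$embedDim
  for (l in seq_len(cfg$numLayers)) {
    for (d in c("f", "b")) {
      pre <- sprintf("lstm%d.%s.", l, d)
      p[[paste0(pre, "Wx")]] <- matrix(runif(inDim * 4 * H, -k, k), inDim, 4 * H)
      p[[paste0(pre, "Wh")]] <- matrix(runif(H * 4 * H, -k, k), H, 4 * H)
      p[[paste0(pre, "b")]] <- runif(4 * H, -k, k)
    }
    inDim <- 2 * H
  }
  p
}

# One direction over a list of B x in inputs (already in this direction's
# time order). Returns per-step hidden states and caches.
lstmDirForward <- function(xs, Wx, Wh, b, keepCache = FALSE) {
  S <- length(xs)
  B <- nrow(xs[[1]])
  H <- ncol(Wh)/ 4L
  hPrev <- matrix(0, B, H)
  cPrev <- matrix(0, B, H)
  hs <- vector("list", S)
  cache <- if (keepCache) vector("list", S) else NULL
  for (t in seq_len(S)) {
    z <- addBias(xs[[t]] %*% Wx + hPrev %*% Wh, b)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, H + 1:H, drop = FALSE])
    g <- tanh(z[, 2 * H + 1:H, drop = FALSE])
    o <- sigmoid(z[, 3 * H + 1:H, drop = FALSE])
    cc <- f * cPrev + i * g
    tc <- tanh(cc)
    h <- o * tc
    if (keepCache) {
      cache[[t]] <- list(x = xs[[t]], hPrev = hPrev, cPrev = cPrev,
                         i = i, f = f, g = g, o = o, c = cc, tc = tc)
    }
    hs[[t]] <- h
    hPrev <- h
    cPrev <- cc
  }
  list(hs = hs, cache = cache)
}

# BPTT for one direction. dhs: list of B x H gradients w.r.t. each step's
# output (zero matrices where no gradient flows in).
lstmDirBackward <- function(dhs, cache, Wx, Wh) {
  S <- length(dhs)
  B <- nrow(dhs[[1]])
  H <- ncol(Wh) / 4L
  dWx <- matrix(0, nrow(Wx), 4 * H)
  dWh <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dxs <- vector("list", S)
  dhNext <- matrix(0, B, H)
  dcNext <- matrix(0, B, H)
  for (t in rev(seq_len(S))) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dhNext
    do <- dh * cc$tc
    dc <- dcNext + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$cPrev
    dcNext <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    dWx <- dWx + t(cc$x) %*% dz
    dWh <- dWh + t(cc$hPrev) %*% dz
    db <- db + colSums(dz)
    dxs[[t]] <- dz %*% t(Wx)
    dhNext <- dz %*% t(Wh)
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

# Full BiLSTM forward: features (Bimg x D) in (sample, step) order with the
# step index fastest. Returns hFinal (B x 2H) and caches.
bilstmForward <- function(features, params, cfg, B, keepCache = FALSE) {
  S <- cfg$seqLen
  H <- cfg$hiddenSize
  xs <- lapply(seq_len(S), function(t) {
    features[(seq_len(B) - 1L) * S + t, , drop = FALSE]
  })
  layers <- vector("list", cfg$numLayers)
  for (l in seq_len(cfg$numLayers)) {
    pf <- sprintf("lstm%d.f.", l)
    pb <- sprintf("lstm%d.b.", l)
    fwd <- lstmDirForward(xs, params[[paste0(pf, "Wx")]],
                          params[[paste0(pf, "Wh")]], params[[paste0(pf, "b")]],
                          keepCache)
    bwd <- lstmDirForward(rev(xs), params[[paste0(pb, "Wx")]],
                          params[[paste0(pb, "Wh")]], params[[paste0(pb, "b")]],
                          keepCache)
    layers[[l]] <- list(fwd = fwd, bwd = bwd)
    # layer output at step t: [h_t^forward ; h_t^backward]
    xs <- lapply(seq_len(S), function(t) {
      cbind(fwd$hs[[t]], bwd$hs[[S - t + 1L]])
    })
  }
  last <- layers[[cfg$numLayers]]
  hFinal <- cbind(last$fwd$hs[[S]], last$bwd$hs[[S]])
  list(hFinal = hFinal,
       cache = if (keepCache) list(layers = layers, S = S, B = B) else NULL)
}

bilstmBackward <- function(dhFinal, cache, params, cfg, grads) {
  S <- cache$S
  B <- cache$B
  H <- cfg$hiddenSize
  L <- cfg$numLayers
  # gradients w.r.t. each layer's per-step concatenated outputs
  dOut <- lapply(seq_len(S), function(t) matrix(0, B, 2 * H))
  dFeat <- NULL
  for (l in rev(seq_len(L))) {
    pf <- sprintf("lstm%d.f.", l)
    pb <- sprintf("lstm%d.b.", l)
    lc <- cache$layers[[l]]
    dhsF <- lapply(seq_len(S), function(t) dOut[[t]][, 1:H, drop = FALSE])
    dhsB <- lapply(seq_len(S), function(t) {
      dOut[[S - t + 1L]][, H + 1:H, drop = FALSE]
    })
    if (l == L) {
      dhsF[[S]] <- dhsF[[S]] + dhFinal[, 1:H, drop = FALSE]
      dhsB[[S]] <- dhsB[[S]] + dhFinal[, H + 1:H, drop = FALSE]
    }
    bf <- lstmDirBackward(dhsF, lc$fwd$cache, params[[paste0(pf, "Wx")]],
                          params[[paste0(pf, "Wh")]])
    bb <- lstmDirBackward(dhsB, lc$bwd$cache, params[[paste0(pb, "Wx")]],
                          params[[paste0(pb, "Wh")]])
    grads[[paste0(pf, "Wx")]] <- grads[[paste0(pf, "Wx")]] + bf$dWx
    grads[[paste0(pf, "Wh")]] <- grads[[paste0(pf, "Wh")]] + bf$dWh
    grads[[paste0(pf, "b")]] <- grads[[paste0(pf, "b")]] + bf$db
    grads[[paste0(pb, "Wx")]] <- grads[[paste0(pb, "Wx")]] + bb$dWx
    grads[[paste0(pb, "Wh")]] <- grads[[paste0(pb, "Wh")]] + bb$dWh
    grads[[paste0(pb, "b")]] <- grads[[paste0(pb, "b")]] + bb$db
    # combine direction input-gradients back to this layer's input steps
    dIn <- lapply(seq_len(S), function(t) {
      bf$dxs[[t]] + bb$dxs[[S - t + 1L]]
    })
    if (l > 1L) dOut <- dIn else dFeat <- dIn
  }
  Bimg <- B * S
  D <- ncol(dFeat[[1]])
  dFeatures <- matrix(0, Bimg, D)
  for (t in seq_len(S)) {
    dFeatures[(seq_len(B) - 1L) * S + t, ] <- dFeat[[t]]
  }
  list(dFeatures = dFeatures, grads = grads)
}
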