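# Vision-transformer encoder over GAF images, batched: the token matrices
# of all images in a minibatch are stacked row-wise so every token-wise
# operation is a single matrix product; only the attention softmax loops
# over images and heads.
#
# Encoder ordering is post-norm:
#   z' = LayerNorm(z + MultiHeadSelfAttention(z))
#   z'' = LayerNorm(z' + FeedForward(z'))
# The image feature is the class-token row after the final layer.

# Precompute, for one H x W image matrix, the linear indices of each patch
# in grid row-major order: a (P*P) x N matrix, column p = pixel indices of
# patch p (column-major within the patch).
patchIndex <- function(imageSize, patchSize) {
  g <- imageSize / patchSize
  N <- g * g
  idx <- matrix(0L, patchSize * patchSize, N)
  p <- 0L
  for (gi in seq_len(g)) {        # patch-grid row
    for (gj in seq_len(g)) {      # patch-grid column
      p <- p + 1L
      rows <- (gi - 1L) * patchSize + seq_len(patchSize)
      cols <- (gj - 1L) * patchSize + seq_len(patchSize)
      idx[, p] <- as.integer(outer(rows, (cols - 1L) * imageSize, `+`))
    }
  }
  idx
}

# images: array (B, S, H, W) of raw 0-255 grayscale planes.
# Returns (B*S*N) x (P^2 * C) patch matrix: image blocks in (b, s) order,
# channels normalised with the configured per-channel mean/sd after
# replicating the grayscale plane.
patchify <- function(images, cfg, idx) {
  d <- dim(images)
  B <- d[1]; S <- d[2]
  N <- ncol(idx); pp <- nrow(idx)
  Bimg <- B * S
  raw <- matrix(0, Bimg * N, pp)
  r <- 0L
  for (b in seq_len(B)) {
    for (s in seq_len(S)) {
      M <- images[b, s, , ] / 255
      raw[r + seq_len(N), ] <- t(matrix(M[as.vector(idx)], pp, N))
      r <- r + N
    }
  }
  cols <- lapply(seq_len(cfg$channels), function(c) {
    (raw - cfg$normMean[c]) / cfg$normStd[c]
  })
  do.call(cbind, cols)
}

# Glorot-normal initialisation for the linear maps keeps the class-token
# representation input-sensitive at depth, which matters when training from
# scratch for a handful of epochs; the positional and class embeddings use
# the customary small-normal (sd 0.02) init.
glorotMat <- function(nIn, nOut) {
  matrix(rnorm(nIn * nOut, sd = sqrt(2 / (nIn + nOut))), nIn, nOut)
}

vitInitParams <- function(cfg) {
  D <- cfg$embedDim
  N <- (cfg$imageSize / cfg$patchSize)^2
  pd <- cfg$patchSize^2 * cfg$channels
  p <- list()
  p[["patch.W"]] <- glorotMat(pd, D)
  p[["patch.b"]] <- numeric(D)
  p[["cls"]] <- rnorm(D, sd = 0.02)
  p[["pos"]] <- matrix(rnorm((N + 1) * D, sd = 0.02), N + 1, D)
  Dm <- cfg$mlpRatio * D
  for (l in seq_len(cfg$depth)) {
    pre <- sprintf("enc%d.", l)
    for (w in c("Wq", "Wk", "Wv", "Wo")) {
      p[[paste0(pre, w)]] <- glorotMat(D, D)
    }
    for (b in c("bq", "bk", "bv", "bo")) p[[paste0(pre, b)]] <- numeric(D)
    p[[paste0(pre, "ln1g")]] <- rep(1, D); p[[paste0(pre, "ln1b")]] <- numeric(D)
    p[[paste0(pre, "mlpW1")]] <- glorotMat(D, Dm)
    p[[paste0(pre, "mlpb1")]] <- numeric(Dm)
    p[[paste0(pre, "mlpW2")]] <- glorotMat(Dm, D)
    p[[paste0(pre, "mlpb2")]] <- numeric(D)
    p[[paste0(pre, "ln2g")]] <- rep(1, D); p[[paste0(pre, "ln2b")]] <- numeric(D)
  }
  p
}

mhsaForward <- function(Z, params, pre, cfg, Bimg, T0, keepCache) {
  D <- cfg$embedDim
  h <- cfg$heads
  dh <- D / h
  scale <- 1 / sqrt(dh)
  Q <- addBias(Z %*% params[[paste0(pre, "Wq")]], params[[paste0(pre, "bq")]])
  K <- addBias(Z %*% params[[paste0(pre, "Wk")]], params[[paste0(pre, "bk")]])
  V <- addBias(Z %*% params[[paste0(pre, "Wv")]], params[[paste0(pre, "bv")]])
  O <- matrix(0, nrow(Z), D)
  attn <- if (keepCache) array(0, dim = c(Bimg, h, T0, T0)) else NULL
  for (b in seq_len(Bimg)) {
    rows <- ((b - 1L) * T0 + 1L):(b * T0)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dh + 1L):(hh * dh)
      S <- (Q[rows, cols, drop = FALSE] %*%
              t(K[rows, cols, drop = FALSE])) * scale
      A <- rowSoftmax(S)
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      if (keepCache) attn[b, hh, , ] <- A
    }
  }
  out <- addBias(O %*% params[[paste0(pre, "Wo")]], params[[paste0(pre, "bo")]])
  list(out = out,
       cache = if (keepCache) list(Zin = Z, Q = Q, K = K, V = V, O = O,
                                   attn = attn) else NULL)
}

mhsaBackward <- function(dOut, cache, params, pre, cfg, Bimg, T0, grads) {
  D <- cfg$embedDim; h <- cfg$heads; dh <- D / h
  scale <- 1 / sqrt(dh)
  Wo <- params[[paste0(pre, "Wo")]]
  grads[[paste0(pre, "Wo")]] <- grads[[paste0(pre, "Wo")]] + t(cache$O) %*% dOut
  grads[[paste0(pre, "bo")]] <- grads[[paste0(pre, "bo")]] + colSums(dOut)
  dO <- dOut %*% t(Wo)
  dQ <- matrix(0, nrow(dO), D); dK <- dQ; dV <- dQ
  for (b in seq_len(Bimg)) {
    rows <- ((b - 1L) * T0 + 1L):(b * T0)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dh + 1L):(hh * dh)
      A <- cache$attn[b, hh, , ]
      dOb <- dO[rows, cols, drop = FALSE]
      v <- cache$V[rows, cols, drop = FALSE]
      dA <- dOb %*% t(v)
      dV[rows, cols] <- t(A) %*% dOb
      dS <- softmaxBackward(dA, A)
      dQ[rows, cols] <- (dS %*% cache$K[rows, cols, drop = FALSE]) * scale
      dK[rows, cols] <- (t(dS) %*% cache$Q[rows, cols, drop = FALSE]) * scale
    }
  }
  Zin <- cache$Zin
  for (nm in list(c("Wq", "bq"), c("Wk", "bk"), c("Wv", "bv"))) {
    dMat <- switch(nm[1], Wq = dQ, Wk = dK, Wv = dV)
    grads[[paste0(pre, nm[1])]] <- grads[[paste0(pre, nm[1])]] + t(Zin) %*% dMat
    grads[[paste0(pre, nm[2])]] <- grads[[paste0(pre, nm[2])]] + colSums(dMat)
  }
  dZ <- dQ %*% t(params[[paste0(pre, "Wq")]]) +
        dK %*% t(params[[paste0(pre, "Wk")]]) +
        dV %*% t(params[[paste0(pre, "Wv")]])
  list(dZ = dZ, grads = grads)
}

# Forward through the full ViT for a stacked batch of images.
# Returns features (Bimg x D class-token rows) and caches for backprop.
vitForward <- function(images, params, cfg, keepCache = FALSE) {
  idx <- patchIndex(cfg$imageSize, cfg$patchSize)
  Xp <- patchify(images, cfg, idx)
  d <- dim(images)
  Bimg <- d[1] * d[2]
  N <- ncol(idx)
  T0 <- N + 1L
  D <- cfg$embedDim
  E <- addBias(Xp %*% params[["patch.W"]], params[["patch.b"]])
  clsRows <- (seq_len(Bimg) - 1L) * T0 + 1L
  patRows <- rep((seq_len(Bimg) - 1L) * T0, each = N) + rep(2:T0, Bimg)
  Z <- matrix(0, Bimg * T0, D)
  Z[clsRows, ] <- matrix(params[["cls"]], Bimg, D, byrow = TRUE)
  Z[patRows, ] <- E
  Z <- Z + params[["pos"]][rep(seq_len(T0), Bimg), , drop = FALSE]
  layers <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    pre <- sprintf("enc%d.", l)
    att <- mhsaForward(Z, params, pre, cfg, Bimg, T0, keepCache)
    R1 <- Z + att$out
    L1 <- lnForward(R1, params[[paste0(pre, "ln1g")]],
                    params[[paste0(pre, "ln1b")]])
    H1 <- addBias(L1$out %*% params[[paste0(pre, "mlpW1")]],
                  params[[paste0(pre, "mlpb1")]])
    G <- gelu(H1)
    Mo <- addBias(G %*% params[[paste0(pre, "mlpW2")]],
                  params[[paste0(pre, "mlpb2")]])
    R2 <- L1$out + Mo
    L2 <- lnForward(R2, params[[paste0(pre, "ln2g")]],
                    params[[paste0(pre, "ln2b")]])
    if (keepCache) {
      layers[[l]] <- list(att = att$cache, L1 = L1,
                          L1out = L1$out, H1 = H1, G = G, L2 = L2)
    }
    Z <- L2$out
  }
  list(features = Z[clsRows, , drop = FALSE],
       cache = if (keepCache) list(Xp = Xp, layers = layers,
                                   clsRows = clsRows, patRows = patRows,
                                   Bimg = Bimg, T0 = T0, N = N) else NULL)
}

# Backward from dFeatures (Bimg x D) to parameter gradients.
vitBackward <- function(dFeatures, cache, params, cfg, grads) {
  Bimg <- cache$Bimg; T0 <- cache$T0; N <- cache$N
  D <- cfg$embedDim
  dZ <- matrix(0, Bimg * T0, D)
  dZ[cache$clsRows, ] <- dFeatures
  for (l in rev(seq_len(cfg$depth))) {
    pre <- sprintf("enc%d.", l)
    lc <- cache$layers[[l]]
    bn2 <- lnBackward(dZ, lc$L2, params[[paste0(pre, "ln2g")]])
    grads[[paste0(pre, "ln2g")]] <- grads[[paste0(pre, "ln2g")]] + bn2$dg
    grads[[paste0(pre, "ln2b")]] <- grads[[paste0(pre, "ln2b")]] + bn2$db
    dR2 <- bn2$dX
    # MLP branch
    dMo <- dR2
    grads[[paste0(pre, "mlpW2")]] <- grads[[paste0(pre, "mlpW2")]] +
      t(lc$G) %*% dMo
    grads[[paste0(pre, "mlpb2")]] <- grads[[paste0(pre, "mlpb2")]] +
      colSums(dMo)
    dG <- dMo %*% t(params[[paste0(pre, "mlpW2")]])
    dH1 <- dG * geluGrad(lc$H1)
    grads[[paste0(pre, "mlpW1")]] <- grads[[paste0(pre, "mlpW1")]] +
      t(lc$L1out) %*% dH1
    grads[[paste0(pre, "mlpb1")]] <- grads[[paste0(pre, "mlpb1")]] +
      colSums(dH1)
    dL1out <- dR2 + dH1 %*% t(params[[paste0(pre, "mlpW1")]])
    bn1 <- lnBackward(dL1out, lc$L1, params[[paste0(pre, "ln1g")]])
    grads[[paste0(pre, "ln1g")]] <- grads[[paste0(pre, "ln1g")]] + bn1$dg
    grads[[paste0(pre, "ln1b")]] <- grads[[paste0(pre, "ln1b")]] + bn1$db
    dR1 <- bn1$dX
    mb <- mhsaBackward(dR1, lc$att, params, pre, cfg, Bimg, T0, grads)
    grads <- mb$grads
    dZ <- dR1 + mb$dZ
  }
  # embedding stage
  grads[["pos"]] <- grads[["pos"]] +
    rowsum(dZ, rep(seq_len(T0), Bimg), reorder = TRUE)
  grads[["cls"]] <- grads[["cls"]] + colSums(dZ[cache$clsRows, , drop = FALSE])
  dE <- dZ[cache$patRows, , drop = FALSE]
  grads[["patch.W"]] <- grads[["patch.W"]] + t(cache$Xp) %*% dE
  grads[["patch.b"]] <- grads[["patch.b"]] + colSums(dE)
  grads
}
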