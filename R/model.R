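# The assembled classifier: ViT spatial encoder -> BiLSTM temporal encoder
# over the per-image class-token features -> dropout + linear + softmax
# head over the three intensity classes.

#' Construct a ViT-BiLSTM classifier
#'
#' The full-size configuration mirrors a base 16-pixel-patch vision
#' transformer at 224 px (embedding 768, depth 12, heads 12) feeding a
#' 2-layer bidirectional LSTM with hidden size 128 (256 concatenated
#' features) and a dropout-0.5 softmax head. The `tiny = TRUE` preset
#' (image 64, patch 8, embedding 32, depth 2, heads 2) is the desk-scale
#' configuration used for from-scratch training in tests and examples.
#' Weights are initialised from scratch; no pretrained weights are loaded.
#'
#' @param imageSize input image side in pixels.
#' @param patchSize patch side in pixels; must divide `imageSize`.
#' @param channels input channels (3; grayscale planes are replicated).
#' @param embedDim transformer embedding width.
#' @param depth number of encoder layers.
#' @param heads attention heads; must divide `embedDim`.
#' @param mlpRatio feed-forward expansion factor.
#' @param hiddenSize LSTM hidden units per direction.
#' @param numLayers stacked LSTM layers.
#' @param seqLen images per classified sequence.
#' @param dropout dropout probability before the output layer.
#' @param normMean,normStd per-channel normalisation applied to pixel
#'   values in `[0, 1]` before patch embedding.
#' @param tiny logical; use the small test configuration.
#' @param seed integer seed for weight initialisation.
#' @return a [ViTBiLSTM-class].
#' @examples
#' m <- vitBilstm(tiny = TRUE, seed = 1)
#' m
#' @export
vitBilstm <- function(imageSize = 224L, patchSize = 16L, channels = 3L,
                      embedDim = 768L, depth = 12L, heads = 12L,
                      mlpRatio = 4L, hiddenSize = 128L, numLayers = 2L,
                      seqLen = 4L, dropout = 0.5,
                      normMean = c(0.3796, 0.3915, 0.8996),
                      normStd = c(0.1860, 0.3054, 0.1428),
                      tiny = FALSE, seed = 1L) {
  if (tiny) {
    imageSize <- 64L; patchSize <- 8L; embedDim <- 32L
    depth <- 2L; heads <- 2L; hiddenSize <- 32L
  }
  if (imageSize %% patchSize != 0) stop("imageSize must be divisible by patchSize")
  if (embedDim %% heads != 0) stop("embedDim must be divisible by heads")
  cfg <- list(imageSize = as.integer(imageSize),
              patchSize = as.integer(patchSize),
              channels = as.integer(channels),
              embedDim = as.integer(embedDim),
              depth = as.integer(depth),
              heads = as.integer(heads),
              mlpRatio = as.integer(mlpRatio),
              hiddenSize = as.integer(hiddenSize),
              numLayers = as.integer(numLayers),
              seqLen = as.integer(seqLen),
              dropout = as.numeric(dropout),
              normMean = rep_len(as.numeric(normMean), channels),
              normStd = rep_len(as.numeric(normStd), channels),
              nClasses = 3L)
  params <- withSeed(seed, {
    p <- c(vitInitParams(cfg), lstmInitParams(cfg))
    p[["head.W"]] <- glorotMat(2 * cfg$hiddenSize, 3)
    p[["head.b"]] <- numeric(3)
    p
  })
  new("ViTBiLSTM", config = cfg, params = params, classes = intensityLevels())
}

#' Model configuration
#' @param model a [ViTBiLSTM-class].
#' @return named list of architecture hyperparameters.
#' @export
modelConfig <- function(model) {
  stopifnot(is(model, "ViTBiLSTM"))
  model@config
}

#' Number of patch tokens per image
#' @param model a [ViTBiLSTM-class].
#' @return integer patch count `(imageSize / patchSize)^2`.
#' @export
numPatches <- function(model) {
  cfg <- modelConfig(model)
  as.integer((cfg$imageSize / cfg$patchSize)^2)
}

# Full forward pass. images: (B, S, H, W) raw 0-255 planes. Training mode
# applies inverted dropout with the supplied mask (B x 2H of 0 / 1/(1-p)).
nnForward <- function(model, images, dropMask = NULL, keepCache = FALSE) {
  cfg <- model@config
  B <- dim(images)[1]
  vit <- vitForward(images, model@params, cfg, keepCache)
  bl <- bilstmForward(vit$features, model@params, cfg, B, keepCache)
  hDrop <- if (is.null(dropMask)) bl$hFinal else bl$hFinal * dropMask
  logits <- addBias(hDrop %*% model@params[["head.W"]],
                    model@params[["head.b"]])
  prob <- rowSoftmax(logits)
  list(logits = logits, prob = prob,
       cache = if (keepCache) list(vit = vit$cache, bl = bl$cache,
                                   hFinal = bl$hFinal, hDrop = hDrop,
                                   dropMask = dropMask) else NULL)
}

# Backward pass from dLogits; returns the flat gradient list.
nnBackward <- function(model, cache, dLogits) {
  cfg <- model@config
  params <- model@params
  grads <- lapply(params, function(p) if (is.matrix(p)) p * 0 else numeric(length(p)))
  grads[["head.W"]] <- t(cache$hDrop) %*% dLogits
  grads[["head.b"]] <- colSums(dLogits)
  dhDrop <- dLogits %*% t(params[["head.W"]])
  dhFinal <- if (is.null(cache$dropMask)) dhDrop else dhDrop * cache$dropMask
  bb <- bilstmBackward(dhFinal, cache$bl, params, cfg, grads)
  grads <- vitBackward(bb$dFeatures, cache$vit, params, cfg, bb$grads)
  grads
}

#' Per-image ViT features
#'
#' Runs only the vision-transformer branch and returns the class-token
#' representation of each image after the final encoder layer.
#'
#' @param model a [ViTBiLSTM-class].
#' @param images array `(n, H, W)` or `(n, S, H, W)` of 0-255 pixel planes.
#' @return matrix with `embedDim` columns, one row per image.
#' @export
vitFeatures <- function(model, images) {
  stopifnot(is(model, "ViTBiLSTM"))
  d <- dim(images)
  if (length(d) == 3L) {
    images <- array(images, dim = c(d[1], 1L, d[2], d[3]))
  }
  vitForward(images, model@params, model@config)$features
}

#' BiLSTM sequence features
#'
#' Encodes an ordered sequence of feature vectors in both directions and
#' returns the concatenation of the two final hidden states.
#'
#' @param model a [ViTBiLSTM-class].
#' @param featureSeq matrix `(seqLen x embedDim)` for one sequence, or an
#'   array `(B, seqLen, embedDim)` for a batch.
#' @return matrix `(B x 2*hiddenSize)`.
#' @export
bilstmFeatures <- function(model, featureSeq) {
  stopifnot(is(model, "ViTBiLSTM"))
  cfg <- model@config
  if (is.matrix(featureSeq)) {
    featureSeq <- array(featureSeq,
                        dim = c(1L, nrow(featureSeq), ncol(featureSeq)))
  }
  d <- dim(featureSeq)
  if (d[2] < 1L) stop("sequence must be nonempty")
  B <- d[1]; S <- d[2]
  flat <- matrix(0, B * S, d[3])
  for (t in seq_len(S)) flat[(seq_len(B) - 1L) * S + t, ] <- featureSeq[, t, ]
  cfgS <- cfg
  cfgS$seqLen <- S
  bilstmForward(flat, model@params, cfgS, B)$hFinal
}

#' @describeIn classify evaluation-mode probabilities and labels for a
#'   SequenceSet.
#' @export
setMethod("classify", signature("ViTBiLSTM", "SequenceSet"),
  function(model, sequences) {
    cfg <- model@config
    d <- dim(sequences@images)
    if (d[2] != cfg$seqLen) {
      stop(sprintf("sequence length %d does not match model seqLen %d",
                   d[2], cfg$seqLen))
    }
    if (d[3] != cfg$imageSize) {
      stop(sprintf("image size %d does not match model imageSize %d",
                   d[3], cfg$imageSize))
    }
    n <- d[1]
    prob <- matrix(0, n, 3, dimnames = list(NULL, model@classes))
    chunk <- 32L
    for (s in seq(1L, n, by = chunk)) {
      e <- min(s + chunk - 1L, n)
      fw <- nnForward(model, sequences@images[s:e, , , , drop = FALSE])
      prob[s:e, ] <- fw$prob
    }
    lab <- factor(model@classes[max.col(prob, ties.method = "first")],
                  levels = model@classes)
    list(prob = prob, label = lab)
  })

#' Save / load a model
#'
#' The weights are written with `saveRDS` next to a JSON sidecar holding
#' the architecture configuration, so the model is fully reconstructable
#' from the pair.
#'
#' @param model a [ViTBiLSTM-class].
#' @param path output path for the weights (`<path>.json` gets the config).
#' @return `path` (`saveModel`) or the restored model (`loadModel`).
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "ViTBiLSTM"))
  saveRDS(model@params, path)
  jsonlite::write_json(model@config, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- readRDS(path)
  cfg$normMean <- as.numeric(cfg$normMean)
  cfg$normStd <- as.numeric(cfg$normStd)
  for (nm in c("imageSize", "patchSize", "channels", "embedDim", "depth",
               "heads", "mlpRatio", "hiddenSize", "numLayers", "seqLen",
               "nClasses")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  new("ViTBiLSTM", config = cfg, params = params,
      classes = intensityLevels())
}
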