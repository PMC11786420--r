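# Dense-layer primitives for the ViT-BiLSTM classifier: linear, layer
# normalisation, GELU, and row softmax, each with a hand-derived backward
# pass. Parameters live in a flat named list of matrices/vectors so the
# Adam update is a simple loop over names.

addBias <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

gelu <- function(x) x * pnorm(x)
geluGrad <- function(x) pnorm(x) + x * dnorm(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise layer normalisation y = (x - mu) / sqrt(var + eps) * g + b.
lnForward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(out = addBias(xhat * matrix(g, nrow(X), length(g), byrow = TRUE), b),
       xhat = xhat, inv = inv)
}

lnBackward <- function(dY, cache, g) {
  xhat <- cache$xhat
  D <- ncol(xhat)
  dxhat <- dY * matrix(g, nrow(dY), length(g), byrow = TRUE)
  dX <- (cache$inv / D) *
    (D * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# softmax backward for row-wise softmax A = softmax(S): dS = A*(dA - rowSums(dA*A))
softmaxBackward <- function(dA, A) A * (dA - rowSums(dA * A))

# Cross-entropy with mean reduction over the batch.
# prob: n x k softmax outputs; y: integer classes 1..k.
crossEntropy <- function(prob, y) {
  -mean(log(pmax(prob[cbind(seq_along(y), y)], 1e-12)))
}

crossEntropyGrad <- function(prob, y) {
  (prob - oneHot(y, ncol(prob))) / length(y)
}
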