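#' 3D convolution with 'same' zero padding
#'
#' Cross-correlation (no kernel flip) over a 5-axis tensor
#' `(batch, channel, d1, d2, d3)` with zero padding `(k - 1) / 2` per side,
#' so that at stride 1 the spatial output size equals the input size. Bias
#' is added per filter.
#'
#' @param X input tensor `(batch, cin, d1, d2, d3)`.
#' @param weights kernel array `(k, k, k, cin, cout)`, `k` odd.
#' @param bias numeric vector of length `cout`.
#' @param stride positive integer stride (same on all axes).
#' @return output tensor `(batch, cout, o1, o2, o3)`.
#' @export
conv3d_same <- function(X, weights, bias, stride = 1L) {
  stopifnot(length(dim(X)) == 5L, length(dim(weights)) == 5L)
  if (dim(weights)[4L] != dim(X)[2L]) {
    stop("conv3d_same: kernel channel depth ", dim(weights)[4L],
         " does not match input channels ", dim(X)[2L])
  }
  cpp_conv3d_forward(X, weights, bias, as.integer(stride))
}

conv3d_backward <- function(X, weights, dY, stride = 1L) {
  cpp_conv3d_backward(X, weights, dY, as.integer(stride))
}

#' 3D max pooling
#'
#' Cubic window of edge `kernel`, valid (zero) padding; output edge per axis
#' is `floor((n - kernel) / stride) + 1`.
#'
#' @param X input tensor `(batch, channel, d1, d2, d3)`.
#' @param kernel window edge length.
#' @param stride positive integer stride.
#' @return list with `Y` (pooled tensor) and `argmax` (flat winner indices,
#'   used by the backward pass).
#' @export
maxpool3d <- function(X, kernel = 2L, stride = 1L) {
  stopifnot(length(dim(X)) == 5L)
  cpp_maxpool3d_forward(X, as.integer(kernel), as.integer(stride))
}

maxpool3d_backward <- function(dY, argmax, dim_x) {
  cpp_maxpool3d_backward(dY, argmax, as.integer(dim_x))
}

#' Batch normalization over a 3D feature map
#'
#' Standardizes each channel over batch and spatial axes using batch
#' statistics in `"train"` mode or running statistics in `"eval"` mode,
#' then applies `scale * xhat + offset`. Running statistics are updated with
#' exponential decay in train mode.
#'
#' @param X input tensor `(batch, channel, d1, d2, d3)`.
#' @param offset,scale per-channel learnables (lengths = channel count).
#' @param state list with `running_mean`, `running_var` per channel.
#' @param mode `"train"` or `"eval"`.
#' @param eps variance floor, default `1e-5`.
#' @param momentum running-statistics decay, default `0.9`
#'   (`new = momentum * old + (1 - momentum) * batch`).
#' @return list with `Y`, updated `state`, and a `cache` for backward.
#' @export
batchnorm3d <- function(X, offset, scale, state, mode = c("train", "eval"),
                        eps = 1e-5, momentum = 0.9) {
  mode <- match.arg(mode)
  d <- dim(X)
  nc <- d[2L]
  stopifnot(length(offset) == nc, length(scale) == nc)
  m <- prod(d) / nc                      # elements per channel
  Xm <- matrix(aperm(X, c(1L, 3L, 4L, 5L, 2L)), nrow = m, ncol = nc)
  if (mode == "train") {
    mu <- colMeans(Xm)
    va <- colMeans(Xm^2) - mu^2          # population variance
    state$running_mean <- momentum * state$running_mean + (1 - momentum) * mu
    state$running_var <- momentum * state$running_var + (1 - momentum) * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(Xm, 2L, mu, "-"), 2L, inv_sd, "*")
  Ym <- sweep(sweep(xhat, 2L, scale, "*"), 2L, offset, "+")
  Y <- aperm(array(Ym, dim = d[c(1L, 3L, 4L, 5L, 2L)]), c(1L, 5L, 2L, 3L, 4L))
  list(Y = Y, state = state,
       cache = list(xhat = xhat, inv_sd = inv_sd, dim = d, scale = scale))
}

batchnorm3d_backward <- function(cache, dY) {
  d <- cache$dim
  nc <- d[2L]
  m <- prod(d) / nc
  dYm <- matrix(aperm(dY, c(1L, 3L, 4L, 5L, 2L)), nrow = m, ncol = nc)
  dscale <- colSums(dYm * cache$xhat)
  doffset <- colSums(dYm)
  # dX = scale * inv_sd * (dY - mean(dY) - xhat * mean(dY * xhat))
  dXm <- sweep(
    sweep(dYm, 2L, doffset / m, "-") -
      sweep(cache$xhat, 2L, dscale / m, "*"),
    2L, cache$scale * cache$inv_sd, "*"
  )
  dX <- aperm(array(dXm, dim = d[c(1L, 3L, 4L, 5L, 2L)]), c(1L, 5L, 2L, 3L, 4L))
  list(dX = dX, doffset = doffset, dscale = dscale)
}

#' Fully connected (dense) layer
#'
#' Affine map `W x + b` applied to each row of a sample-by-feature matrix.
#'
#' @param x numeric vector (one sample) or matrix `(samples, features)`.
#' @param W weight matrix `(out, in)`.
#' @param b bias vector of length `out`.
#' @return matrix `(samples, out)` (a vector input yields a vector).
#' @export
fully_connected <- function(x, W, b) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, nrow = 1L) else x
  if (ncol(xm) != ncol(W)) {
    stop("fully_connected: input width ", ncol(xm),
         " does not match weight width ", ncol(W))
  }
  out <- tcrossprod(xm, W) + matrix(b, nrow(xm), length(b), byrow = TRUE)
  if (vec) drop(out) else out
}

fully_connected_backward <- function(x, W, dY) {
  xm <- if (is.null(dim(x))) matrix(x, nrow = 1L) else x
  dYm <- if (is.null(dim(dY))) matrix(dY, nrow = 1L) else dY
  list(dX = dYm %*% W, dW = crossprod(dYm, xm), db = colSums(dYm))
}

# Inverted dropout: eval is the identity.
dropout_forward <- function(X, rate, mode) {
  if (mode != "train" || rate <= 0) {
    return(list(Y = X, mask = NULL))
  }
  mask <- array(stats::runif(length(X)) >= rate, dim = dim(X)) / (1 - rate)
  list(Y = X * mask, mask = mask)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Standard baseline activations selectable per slot.
activation_forward <- function(name, X, params = NULL) {
  switch(name,
    sgt = sgt_forward(X, params),
    relu = list(Z = pmax(X, 0), cache = list(X = X)),
    leaky_relu = list(Z = ifelse(X > 0, X, 0.01 * X), cache = list(X = X)),
    tanh = list(Z = tanh(X), cache = list(X = X)),
    swish = {
      s <- 1 / (1 + exp(-X))
      list(Z = X * s, cache = list(X = X, s = s))
    },
    stop("unknown activation '", name, "'")
  )
}

activation_backward <- function(name, cache, dLdZ, params = NULL) {
  switch(name,
    sgt = sgt_backward_input(cache, dLdZ, params),
    relu = dLdZ * (cache$X > 0),
    leaky_relu = dLdZ * ifelse(cache$X > 0, 1, 0.01),
    tanh = dLdZ * (1 - tanh(cache$X)^2),
    swish = {
      s <- cache$s
      dLdZ * (s + cache$X * s * (1 - s))
    },
    stop("unknown activation '", name, "'")
  )
}
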