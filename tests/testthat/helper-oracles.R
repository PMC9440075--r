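# Independent scalar oracles and small fixtures shared across tests.

# Literal per-element evaluation of the activation's backward rules using
# complex arithmetic (R's principal-branch complex power and log), looped
# element by element. Independent of the vectorized implementation.
oracle_sgt_backward <- function(X, dLdZ, alpha, beta, a = 0.1, b = 1.1) {
  d <- dim(X)
  nc <- length(alpha)
  dX <- array(0, dim = d)
  da <- numeric(nc)
  db <- numeric(nc)
  for (bi in seq_len(d[1])) for (n in seq_len(d[2])) {
    for (i in seq_len(d[3])) for (j in seq_len(d[4])) for (k in seq_len(d[5])) {
      x <- X[bi, n, i, j, k]
      g <- dLdZ[bi, n, i, j, k]
      xg <- if (x == 0) 0.001 else x
      if (x < 0) {
        yp <- a * alpha[n] * Re((xg + 0i)^(abs(alpha[n]) - 1))
        da[n] <- da[n] + a * Re(log10(xg + 0i)) * Re((xg + 0i)^abs(alpha[n])) * g
      } else {
        yp <- b * beta[n] * Re((xg + 0i)^(abs(beta[n]) - 1))
        if (x > 0) {
          db[n] <- db[n] + b * Re(log10(xg + 0i)) * Re((xg + 0i)^abs(beta[n])) * g
        }
      }
      dX[bi, n, i, j, k] <- (1 / cosh(yp)^2) * g
    }
  }
  list(dX = dX, dalpha = da, dbeta = db)
}

# Random 5-axis tensor with entries bounded away from zero (for derivative
# checks) unless allow_zero.
random_tensor <- function(dims, seed, min_abs = 0) {
  set.seed(seed)
  v <- runif(prod(dims), min_abs, 1.5) * sample(c(-1, 1), prod(dims), TRUE)
  array(v, dim = dims)
}

# A tiny trainable architecture used by network-level tests.
tiny_spec <- function(edge = 12L, channels = 2L, dropout = 0) {
  divnet_spec(edge = edge, channels = channels, classes = 3L,
              dropout = dropout)
}

# Numerical loss gradient for one flat parameter entry.
fd_loss_grad <- function(network, key, i, lossfun, eps = 1e-5) {
  p <- sgtnet:::get_params(network)
  p[[key]][i] <- p[[key]][i] + eps
  lp <- lossfun(sgtnet:::set_params(network, p))
  p[[key]][i] <- p[[key]][i] - 2 * eps
  lm <- lossfun(sgtnet:::set_params(network, p))
  (lp - lm) / (2 * eps)
}
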