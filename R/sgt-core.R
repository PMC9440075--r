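#' Real-part power for possibly negative bases
#'
#' Raises `x` to the power `p`, keeping only the real part of the
#' principal-branch complex power when the base is negative:
#' for `x < 0`, `real_power(x, p) = |x|^p * cos(pi * p)`. For `x >= 0` the
#' ordinary power is returned. This is the convention under which a unit
#' exponent recovers the identity on the negative axis (`(-0.5)^1 = -0.5`),
#' so the activation degenerates to a Leaky-ReLU-like curve when its
#' exponents equal 1.
#'
#' @param x numeric scalar or array (any shape).
#' @param p single finite numeric exponent.
#' @return object shaped like `x`.
#' @examples
#' real_power(4, 0.5)     # 2
#' real_power(-0.5, 1)    # -0.5
#' real_power(-0.5, 0.5)  # 0: |x|^p * cos(pi/2)
#' @export
real_power <- function(x, p) {
  stopifnot(is.numeric(p), length(p) == 1L, is.finite(p))
  if (p < 0) {
    bad <- which(x == 0)
    if (length(bad)) {
      stop("real_power: zero base with negative exponent at index ",
           bad[1L], "; apply zero_guard() first")
    }
  }
  out <- x
  neg <- x < 0
  out[!neg] <- x[!neg]^p
  if (any(neg)) out[neg] <- abs(x[neg])^p * cos(pi * p)
  out
}

#' Replace exact zeros by a small constant
#'
#' The backward rules involve `log10(x)` and powers with negative exponents,
#' both indeterminate at 0. Every entry exactly equal to 0 is replaced by
#' 0.001 (the guard used throughout this package); all other entries are
#' untouched. Forward evaluation never needs the guard.
#'
#' @param v numeric scalar or array.
#' @param guard replacement value for exact zeros.
#' @return `v` with zeros replaced.
#' @export
zero_guard <- function(v, guard = 0.001) {
  v[v == 0] <- guard
  v
}

#' Construct per-layer SGT parameters
#'
#' An SGT layer holds two fixed branch gains (`a` for the negative branch,
#' `b` for the positive branch) and two learnable per-channel exponent
#' vectors `alpha` (negative branch) and `beta` (positive branch).
#'
#' @param alpha,beta numeric exponent vectors, one entry per channel; equal
#'   length required.
#' @param a,b positive branch gains; defaults 0.1 and 1.1.
#' @return an object of class `sgt_params`.
#' @examples
#' p <- sgt_params(alpha = rep(1, 4), beta = rep(1, 4))
#' @export
sgt_params <- function(alpha, beta, a = 0.1, b = 1.1) {
  stopifnot(
    is.numeric(alpha), is.numeric(beta), length(alpha) == length(beta),
    all(is.finite(alpha)), all(is.finite(beta)),
    length(a) == 1L, length(b) == 1L, a > 0, b > 0
  )
  structure(
    list(a = a, b = b, alpha = as.numeric(alpha), beta = as.numeric(beta)),
    class = "sgt_params"
  )
}

#' @export
print.sgt_params <- function(x, ...) {
  cat("SGT parameters:", length(x$alpha), "channel(s); a =", x$a,
      ", b =", x$b, "\n")
  cat("  alpha range: [", min(x$alpha), ",", max(x$alpha), "]\n")
  cat("  beta  range: [", min(x$beta), ",", max(x$beta), "]\n")
  invisible(x)
}

# Broadcast a per-channel vector over a (batch, channel, d1, d2, d3) array.
# Axis 2 is the canonical channel axis; a plain vector input (single-channel
# convenience) broadcasts entry 1.
channel_expand <- function(v, dim_x) {
  if (length(dim_x) < 2L) return(rep(v[1L], prod(dim_x)))
  per <- dim_x[1L]                      # batch runs fastest
  rest <- prod(dim_x[-(1:2)])
  rep(rep(v, each = per), times = rest)
}

check_channels <- function(X, params) {
  d <- dim(X)
  nc <- length(params$alpha)
  if (is.null(d)) {
    if (nc != 1L) {
      stop("sgt: input has no channel axis but params carry ", nc, " channels")
    }
  } else if (d[2L] != nc) {
    stop("sgt: channel axis length ", d[2L], " does not match ",
         nc, " parameter channels")
  }
  invisible(TRUE)
}

#' SGT forward, step 1: learnable gamma correction
#'
#' Applies the channel-wise power-law transform
#' `y = a * x^|alpha_n|` for `x < 0` and `y = b * x^|beta_n|` for `x >= 0`,
#' with negative bases handled by [real_power()]. Absolute values of the
#' exponents are taken so the power is always a positive-exponent gamma
#' correction; at `x = 0` both branches give 0, so the point is assigned to
#' the positive branch.
#'
#' @param X numeric array, canonically 5-axis `(batch, channel, d1, d2, d3)`;
#'   scalars/vectors are treated as single-channel.
#' @param params an [sgt_params()] object whose vectors match the channel
#'   axis of `X`.
#' @return array shaped like `X`.
#' @export
sgt_step1 <- function(X, params) {
  check_channels(X, params)
  d <- dim(X)
  al <- channel_expand(abs(params$alpha), if (is.null(d)) length(X) else d)
  be <- channel_expand(abs(params$beta), if (is.null(d)) length(X) else d)
  x <- as.numeric(X)
  y <- numeric(length(x))
  neg <- x < 0
  if (any(neg)) {
    y[neg] <- params$a * abs(x[neg])^al[neg] * cos(pi * al[neg])
  }
  if (any(!neg)) y[!neg] <- params$b * x[!neg]^be[!neg]
  dim(y) <- d
  y
}

#' SGT forward, step 2: tanh squash
#'
#' Elementwise hyperbolic tangent; output strictly inside (-1, 1).
#'
#' @param Y numeric array.
#' @return array shaped like `Y`.
#' @export
sgt_step2 <- function(Y) tanh(Y)

#' Full SGT forward pass
#'
#' Composes [sgt_step1()] and [sgt_step2()] and returns the activation
#' together with the cache needed by the backward rules.
#'
#' @inheritParams sgt_step1
#' @return list with `Z` (the activation, same shape as `X`) and `cache`
#'   (holding `X` and the intermediate `Y`).
#' @examples
#' p <- sgt_params(alpha = 1, beta = 1)
#' sgt_forward(0.5, p)$Z   # tanh(0.55)
#' @export
sgt_forward <- function(X, params) {
  Y <- sgt_step1(X, params)
  list(Z = sgt_step2(Y), cache = list(X = X, Y = Y))
}

# Step-1 derivative Y' as used by the layer's backward rule:
#   Y' = a * alpha * real(X^(|alpha|-1))  for X < 0
#   Y' = b * beta  * real(X^(|beta|-1))   for X >= 0
# X is zero-guarded (the |.|-1 exponent can be negative); the exponent uses
# the absolute parameter value while the multiplicative factor keeps its raw
# sign by default (sech^2 is even, so the sign never reaches the input
# gradient; it is kept switchable for the parameter-free diagnostics).
sgt_step1_deriv <- function(X, params, abs_multiplier = FALSE) {
  check_channels(X, params)
  d <- dim(X)
  dims <- if (is.null(d)) length(X) else d
  mul_a <- if (abs_multiplier) abs(params$alpha) else params$alpha
  mul_b <- if (abs_multiplier) abs(params$beta) else params$beta
  al <- channel_expand(abs(params$alpha), dims)
  be <- channel_expand(abs(params$beta), dims)
  ma <- channel_expand(mul_a, dims)
  mb <- channel_expand(mul_b, dims)
  x <- zero_guard(as.numeric(X))
  neg <- as.numeric(X) < 0
  yp <- numeric(length(x))
  if (any(neg)) {
    p <- al[neg] - 1
    yp[neg] <- params$a * ma[neg] * abs(x[neg])^p * cos(pi * p)
  }
  if (any(!neg)) yp[!neg] <- params$b * mb[!neg] * x[!neg]^(be[!neg] - 1)
  dim(yp) <- d
  yp
}

sech2 <- function(x) 1 / cosh(x)^2

#' SGT backward rule for the layer input (the training default)
#'
#' Implements the layer's literal input-gradient rule: the step-1 derivative
#' `Y'` is computed branch-wise, and the returned gradient is
#' `sech^2(Y') * dLdZ`. Note that `sech^2` is applied to the *derivative*
#' `Y'` itself, not to the pre-tanh value `Y`; this is deliberately not the
#' exact chain rule (see [sgt_true_gradient()] for that). With both
#' exponents at 1 the factor is the constant `sech^2(1.1) = 0.3592` on the
#' positive branch and `sech^2(0.1) = 0.99006` on the negative branch.
#'
#' @param cache cache list from [sgt_forward()].
#' @param dLdZ upstream gradient, same shape as the forward input.
#' @param params an [sgt_params()] object.
#' @param abs_multiplier if `TRUE`, the multiplicative exponent factor in
#'   `Y'` uses `|alpha|`/`|beta|` rather than the raw signed values.
#'   Immaterial to the result (`sech^2` is even) but kept switchable.
#' @return gradient array shaped like the forward input.
#' @export
sgt_backward_input <- function(cache, dLdZ, params, abs_multiplier = FALSE) {
  X <- cache$X
  if (!identical(length(X), length(dLdZ))) {
    stop("sgt_backward_input: gradient shape does not match forward input")
  }
  yp <- sgt_step1_deriv(X, params, abs_multiplier = abs_multiplier)
  sech2(yp) * dLdZ
}

#' SGT backward rule for the learnable exponents
#'
#' Per channel `n`, accumulates over the batch and all spatial positions:
#' `dL/dalpha_n = sum_{x<0} a * log10|x| * real(x^|alpha_n|) * dLdZ` and
#' `dL/dbeta_n = sum_{x>0} b * log10(x) * real(x^|beta_n|) * dLdZ`,
#' with `x` zero-guarded before logs and powers. The base-10 logarithm is
#' the layer's printed update rule and is kept verbatim (an exact-calculus
#' alternative exists only as a diagnostic, see [sgt_true_gradient()]).
#'
#' @inheritParams sgt_backward_input
#' @return list with per-channel vectors `dalpha` and `dbeta`.
#' @export
sgt_backward_params <- function(cache, dLdZ, params) {
  X <- cache$X
  if (!identical(length(X), length(dLdZ))) {
    stop("sgt_backward_params: gradient shape does not match forward input")
  }
  d <- dim(X)
  dims <- if (is.null(d)) length(X) else d
  nc <- length(params$alpha)
  al <- channel_expand(abs(params$alpha), dims)
  be <- channel_expand(abs(params$beta), dims)
  ch <- channel_expand(seq_len(nc), dims)
  x <- zero_guard(as.numeric(X))
  g <- as.numeric(dLdZ)
  neg <- as.numeric(X) < 0
  pos <- as.numeric(X) > 0
  da <- numeric(nc)
  db <- numeric(nc)
  if (any(neg)) {
    term <- params$a * log10(abs(x[neg])) *
      (abs(x[neg])^al[neg] * cos(pi * al[neg])) * g[neg]
    acc <- rowsum(term, group = ch[neg])
    da[as.integer(rownames(acc))] <- acc[, 1L]
  }
  if (any(pos)) {
    term <- params$b * log10(x[pos]) * x[pos]^be[pos] * g[pos]
    acc <- rowsum(term, group = ch[pos])
    db[as.integer(rownames(acc))] <- acc[, 1L]
  }
  list(dalpha = da, dbeta = db)
}

#' Exact chain-rule input gradient (diagnostic mode)
#'
#' Returns `sech^2(Y) * (dY/dX) * dLdZ`, the calculus-correct gradient of
#' `tanh(step1(x))`. Used only for finite-difference validation and for
#' quantifying how far the training-default rule
#' ([sgt_backward_input()]) departs from it; never the training default.
#'
#' @inheritParams sgt_backward_input
#' @return gradient array shaped like the forward input.
#' @export
sgt_true_gradient <- function(cache, dLdZ, params) {
  yp <- sgt_step1_deriv(cache$X, params, abs_multiplier = FALSE)
  sech2(cache$Y) * yp * dLdZ
}
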