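test_that("real_power keeps the real part of the principal complex branch", {
  expect_equal(real_power(4, 0.5), 2)
  expect_equal(real_power(-0.5, 1), -0.5)
  # |x|^p * cos(pi p) at p = 1/2 vanishes; oracle: complex arithmetic
  expect_equal(real_power(-0.5, 0.5), Re((-0.5 + 0i)^0.5), tolerance = 1e-14)
  expect_equal(real_power(-0.5, 0.5), 0, tolerance = 1e-15)
  # vectorized over mixed signs agrees with elementwise complex evaluation
  x <- c(-1.3, -0.2, 0, 0.7, 2.1)
  p <- 0.37
  expect_equal(real_power(x, p), Re((x + 0i)^p), tolerance = 1e-13)
  expect_error(real_power(c(1, 0), -1), "zero_guard")
})

test_that("zero_guard replaces exact zeros only", {
  expect_identical(zero_guard(0), 0.001)
  expect_identical(zero_guard(0.5), 0.5)
  expect_identical(zero_guard(c(-1, 0, 2)), c(-1, 0.001, 2))
  expect_identical(zero_guard(1e-300), 1e-300)  # tiny but non-zero untouched
})

test_that("step 1 applies the two-branch gamma transform per channel", {
  p <- sgt_params(alpha = 1, beta = 1)
  expect_equal(sgt_step1(0.5, p), 0.55)
  expect_equal(sgt_step1(-0.5, p), -0.05)
  p_half <- sgt_params(alpha = 0.5, beta = 1)
  expect_equal(sgt_step1(-0.5, p_half), 0, tolerance = 1e-15)
  # negative exponents enter as their absolute values
  p_neg <- sgt_params(alpha = -0.5, beta = -2)
  expect_equal(sgt_step1(c(-0.5, 0.5), p_neg),
               sgt_step1(c(-0.5, 0.5), sgt_params(alpha = 0.5, beta = 2)))
  # channel mismatch is a contract error
  X <- array(1, dim = c(1, 3, 2, 2, 2))
  expect_error(sgt_step1(X, sgt_params(alpha = rep(1, 2), beta = rep(1, 2))),
               "channel")
})

test_that("per-channel exponents act on their own channel only", {
  X <- array(0.5, dim = c(2, 3, 2, 2, 2))
  p <- sgt_params(alpha = c(1, 1, 1), beta = c(1, 2, 3))
  Y <- sgt_step1(X, p)
  for (n in 1:3) {
    expect_equal(unique(as.numeric(Y[, n, , , ])), 1.1 * 0.5^n,
                 tolerance = 1e-14)
  }
})

test_that("forward composes gamma correction with tanh and stays in (-1, 1)", {
  p <- sgt_params(alpha = 1, beta = 1)
  expect_equal(sgt_forward(0.5, p)$Z, tanh(0.55), tolerance = 1e-12)
  expect_equal(sgt_forward(0.5, p)$Z, 0.5005, tolerance = 1e-4)
  expect_equal(sgt_forward(0, p)$Z, 0)
  # identity limit: a = b = 1, alpha = beta = 1 reduces to tanh exactly
  pid <- sgt_params(alpha = c(1, 1), beta = c(1, 1), a = 1, b = 1)
  X <- random_tensor(c(2, 2, 3, 3, 3), seed = 11)
  expect_equal(sgt_forward(X, pid)$Z, tanh(X), tolerance = 1e-15)
  # boundedness and saturation: strictly inside (-1, 1) at moderate inputs,
  # saturating towards +/-1 (to machine precision) for large ones
  pr <- sgt_params(alpha = c(0.4, 1.7), beta = c(0.9, 2.3))
  Xb <- random_tensor(c(2, 2, 3, 3, 3), seed = 12)
  Z <- sgt_forward(Xb, pr)$Z
  expect_true(all(abs(Z) < 1))
  Zbig <- sgt_forward(Xb * 50, pr)$Z
  expect_true(all(abs(Zbig) <= 1))
  expect_equal(sgt_forward(1e6, p)$Z, 1, tolerance = 1e-9)
})

test_that("forward is non-decreasing on the positive axis", {
  for (beta in c(0.3, 1, 2.4)) {
    p <- sgt_params(alpha = 1, beta = beta)
    x <- seq(0, 5, length.out = 200)
    z <- as.numeric(sgt_forward(x, p)$Z)
    expect_true(all(diff(z) >= 0))
  }
})

test_that("backward input rule gives the printed constants at unit exponents", {
  p <- sgt_params(alpha = 1, beta = 1)
  fpos <- sgt_forward(0.5, p)
  fneg <- sgt_forward(-0.3, p)
  gpos <- sgt_backward_input(fpos$cache, 1, p)
  gneg <- sgt_backward_input(fneg$cache, 1, p)
  expect_equal(gpos, 1 / cosh(1.1)^2, tolerance = 1e-14)
  expect_equal(gneg, 1 / cosh(0.1)^2, tolerance = 1e-14)
  expect_equal(round(gpos, 4), 0.3592)
  expect_equal(gneg, 0.99006, tolerance = 1e-5)
  # linear in the upstream gradient
  expect_equal(sgt_backward_input(fpos$cache, 0, p), 0)
  expect_equal(sgt_backward_input(fpos$cache, 2.5, p), 2.5 * gpos)
})

test_that("backward rule is invariant to exponent sign flips (sech^2 even)", {
  X <- random_tensor(c(2, 3, 3, 3, 3), seed = 21, min_abs = 0.05)
  dZ <- random_tensor(c(2, 3, 3, 3, 3), seed = 22)
  al <- c(0.7, 1.3, 0.4)
  be <- c(1.1, 0.6, 2.0)
  p1 <- sgt_params(alpha = al, beta = be)
  p2 <- sgt_params(alpha = -al, beta = -be)
  f1 <- sgt_forward(X, p1)
  f2 <- sgt_forward(X, p2)
  expect_equal(sgt_backward_input(f1$cache, dZ, p1),
               sgt_backward_input(f2$cache, dZ, p2), tolerance = 1e-14)
})

test_that("parameter gradients match hand evaluation and vanish off-branch", {
  p <- sgt_params(alpha = 1, beta = 1)
  f <- sgt_forward(0.5, p)
  g <- sgt_backward_params(f$cache, 1, p)
  expect_equal(g$dbeta, 1.1 * log10(0.5) * 0.5, tolerance = 1e-12)
  expect_equal(g$dbeta, -0.16557, tolerance = 1e-4)
  expect_equal(g$dalpha, 0)  # no negative inputs
  # all-positive input leaves dalpha at zero per channel
  X <- array(abs(random_tensor(c(2, 2, 2, 2, 2), seed = 31)), c(2, 2, 2, 2, 2))
  dZ <- array(1, dim = dim(X))
  fb <- sgt_forward(X, sgt_params(alpha = c(1, 2), beta = c(1, 2)))
  gb <- sgt_backward_params(fb$cache, dZ, sgt_params(alpha = c(1, 2), beta = c(1, 2)))
  expect_equal(gb$dalpha, c(0, 0))
  # zero upstream gradient kills both
  g0 <- sgt_backward_params(fb$cache, dZ * 0, sgt_params(alpha = c(1, 2), beta = c(1, 2)))
  expect_equal(g0$dalpha, c(0, 0))
  expect_equal(g0$dbeta, c(0, 0))
})

test_that("vectorized backward equals the scalar per-element oracle", {
  for (seed in c(41, 42, 43)) {
    X <- random_tensor(c(2, 4, 3, 3, 3), seed = seed)
    X[sample(length(X), 5)] <- 0   # exercise the zero guard
    dZ <- random_tensor(c(2, 4, 3, 3, 3), seed = seed + 100)
    al <- runif(4, -1, 1.5)
    be <- runif(4, -1, 1.5)
    p <- sgt_params(alpha = al, beta = be)
    f <- sgt_forward(X, p)
    ora <- oracle_sgt_backward(X, dZ, al, be)
    expect_equal(sgt_backward_input(f$cache, dZ, p), ora$dX, tolerance = 1e-12)
    pg <- sgt_backward_params(f$cache, dZ, p)
    expect_equal(pg$dalpha, ora$dalpha, tolerance = 1e-12)
    expect_equal(pg$dbeta, ora$dbeta, tolerance = 1e-12)
  }
})

test_that("true-gradient mode matches finite differences away from zero", {
  X <- random_tensor(c(2, 3, 3, 3, 3), seed = 51, min_abs = 0.2)
  p <- sgt_params(alpha = c(0.8, 1.4, 0.5), beta = c(1.2, 0.7, 1.9))
  f <- sgt_forward(X, p)
  dZ <- array(1, dim = dim(X))
  g <- sgt_true_gradient(f$cache, dZ, p)
  eps <- 1e-6
  num <- (sgt_forward(X + eps, p)$Z - sgt_forward(X - eps, p)$Z) / (2 * eps)
  expect_equal(as.numeric(g), as.numeric(num), tolerance = 1e-5)
})

test_that("true gradient and layer rule deliberately diverge", {
  # at unit exponents the layer rule is piecewise constant while the true
  # gradient is sech^2 of the pre-tanh value
  p <- sgt_params(alpha = c(1, 1), beta = c(1, 1), a = 1, b = 1)
  X <- random_tensor(c(2, 2, 2, 2, 2), seed = 61, min_abs = 0.1)
  f <- sgt_forward(X, p)
  dZ <- array(1, dim = dim(X))
  expect_equal(sgt_true_gradient(f$cache, dZ, p), (1 / cosh(X)^2) * dZ,
               tolerance = 1e-13)
  expect_gt(max(abs(sgt_true_gradient(f$cache, dZ, p) -
                    sgt_backward_input(f$cache, dZ, p))), 0.01)
})
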