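# Numerical checks of the hand-written layer primitives against a naive
# direct convolution and central finite differences. These guard the
# training path: a wrong backward pass would silently stall learning.

naive_conv <- function(x, w, b, stride, pad, dil) {
  d <- dim(x)
  wd <- dim(w)
  eff <- dil * (wd[1] - 1) + 1
  Ho <- (d[1] + 2 * pad - eff) %/% stride + 1
  Wo <- (d[2] + 2 * pad - eff) %/% stride + 1
  out <- array(0, c(Ho, Wo, wd[4], d[4]))
  for (n in 1:d[4]) for (co in 1:wd[4]) for (oi in 1:Ho) for (oj in 1:Wo) {
    acc <- b[co]
    for (c in 1:d[3]) for (ki in 1:wd[1]) for (kj in 1:wd[2]) {
      i <- (oi - 1) * stride - pad + (ki - 1) * dil + 1
      j <- (oj - 1) * stride - pad + (kj - 1) * dil + 1
      if (i >= 1 && i <= d[1] && j >= 1 && j <= d[2])
        acc <- acc + x[i, j, c, n] * w[ki, kj, c, co]
    }
    out[oi, oj, co, n] <- acc
  }
  out
}

num_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("convolution forward matches a direct-evaluation oracle", {
  set.seed(42)
  cases <- list(list(k = 3, s = 1, p = 1, dl = 1),
                list(k = 3, s = 2, p = 1, dl = 1),
                list(k = 3, s = 1, p = 2, dl = 2),
                list(k = 7, s = 2, p = 3, dl = 1))
  for (cs in cases) {
    x <- array(rnorm(9 * 9 * 3 * 2), c(9, 9, 3, 2))
    w <- array(rnorm(cs$k^2 * 3 * 4), c(cs$k, cs$k, 3, 4))
    b <- rnorm(4)
    expect_equal(apnn:::conv2d_fw_cpp(x, w, b, cs$s, cs$p, cs$dl),
                 naive_conv(x, w, b, cs$s, cs$p, cs$dl), tolerance = 1e-12)
  }
})

test_that("convolution and pooling backward match finite differences", {
  set.seed(7)
  x <- array(rnorm(7 * 7 * 2 * 2), c(7, 7, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  G <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  bw <- apnn:::conv2d_bw_cpp(x, w, G, 2L, 1L, 1L)
  fx <- function(v) sum(apnn:::conv2d_fw_cpp(array(v, dim(x)), w, b, 2L, 1L, 1L) * G)
  fw <- function(v) sum(apnn:::conv2d_fw_cpp(x, array(v, dim(w)), b, 2L, 1L, 1L) * G)
  expect_lt(max(abs(as.numeric(bw$gx) - num_grad(fx, as.numeric(x)))), 1e-6)
  expect_lt(max(abs(as.numeric(bw$gw) - num_grad(fw, as.numeric(w)))), 1e-6)

  mp <- apnn:::maxpool_fw_cpp(x, 3L, 2L, 1L)
  Gm <- array(rnorm(length(mp$out)), dim(mp$out))
  gx <- apnn:::maxpool_bw_cpp(mp$argmax, Gm, dim(x))
  fm <- function(v) sum(apnn:::maxpool_fw_cpp(array(v, dim(x)), 3L, 2L, 1L)$out * Gm)
  expect_lt(max(abs(as.numeric(gx) - num_grad(fm, as.numeric(x)))), 1e-6)
})

test_that("batch-norm and residual blocks backpropagate correctly", {
  set.seed(8)
  ly <- apnn:::bn_layer(3)
  x <- array(rnorm(5 * 5 * 3 * 4), c(5, 5, 3, 4))
  G <- array(rnorm(length(x)), dim(x))
  fwd <- apnn:::bn_fw(ly, x, TRUE)
  bwd <- apnn:::bn_bw(ly, fwd$cache, G)
  fx <- function(v) sum(apnn:::bn_fw(ly, array(v, dim(x)), TRUE)$out * G)
  expect_lt(max(abs(as.numeric(bwd$dx) - num_grad(fx, as.numeric(x)))), 1e-5)

  rb <- apnn:::res_layer(2, 3, 2)
  xr <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  fr <- apnn:::res_fw(rb, xr, TRUE)
  Gr <- array(rnorm(length(fr$out)), dim(fr$out))
  br <- apnn:::res_bw(rb, fr$cache, Gr)
  fxr <- function(v) sum(apnn:::res_fw(rb, array(v, dim(xr)), TRUE)$out * Gr)
  expect_lt(max(abs(as.numeric(br$dx) - num_grad(fxr, as.numeric(xr)))), 1e-5)
})

test_that("attention blocks backpropagate correctly", {
  set.seed(9)
  x <- array(rnorm(5 * 5 * 4 * 3), c(5, 5, 4, 3))
  for (mk in list(function() apnn:::ca_layer(4, r = 2, L = 2),
                  function() apnn:::sa_layer(),
                  function() apnn:::cbam_layer(4, r = 2, L = 2))) {
    ly <- mk()
    fwd <- switch(ly$type, ca = apnn:::ca_fw(ly, x, TRUE),
                  sa = apnn:::sa_fw(ly, x, TRUE),
                  cbam = apnn:::cbam_fw(ly, x, TRUE))
    G <- array(rnorm(length(fwd$out)), dim(fwd$out))
    bwd <- switch(ly$type, ca = apnn:::ca_bw(ly, fwd$cache, G),
                  sa = apnn:::sa_bw(ly, fwd$cache, G),
                  cbam = apnn:::cbam_bw(ly, fwd$cache, G))
    f <- function(v) {
      o <- switch(ly$type, ca = apnn:::ca_fw(ly, array(v, dim(x)), TRUE),
                  sa = apnn:::sa_fw(ly, array(v, dim(x)), TRUE),
                  cbam = apnn:::cbam_fw(ly, array(v, dim(x)), TRUE))
      sum(o$out * G)
    }
    expect_lt(max(abs(as.numeric(bwd$dx) - num_grad(f, as.numeric(x)))), 1e-5)
  }
})
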