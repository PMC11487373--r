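# Layer primitives for the embedding network.
#
# A layer is a list with fields:
#   type  - one of "conv", "bn", "relu", "maxpool", "res", "ca", "sa", "cbam"
#   par   - named list of trainable arrays (may be absent)
#   sub   - named list of sub-layers (may be absent; NULL entries allowed)
#   state - non-trainable state (batch-norm running moments)
# A network is an unnamed list of layers. Forward passes thread the (possibly
# state-updated) layer back to the caller so running statistics accumulate.

conv_layer <- function(k, cin, cout, stride = 1, pad = 0, dil = 1) {
  w <- array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
             c(k, k, cin, cout))
  list(type = "conv", par = list(w = w, b = numeric(cout)),
       stride = as.integer(stride), pad = as.integer(pad), dil = as.integer(dil))
}

bn_layer <- function(C) {
  list(type = "bn", par = list(gamma = rep(1, C), beta = rep(0, C)),
       state = list(rm = rep(0, C), rv = rep(1, C)))
}

relu_layer <- function() list(type = "relu")

maxpool_layer <- function(k, stride, pad = 0) {
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}

# Basic residual block (two 3x3 conv-bn, identity or 1x1 projection shortcut).
res_layer <- function(cin, cout, stride = 1) {
  sub <- list(conv1 = conv_layer(3, cin, cout, stride, 1),
              bn1 = bn_layer(cout),
              conv2 = conv_layer(3, cout, cout, 1, 1),
              bn2 = bn_layer(cout))
  if (stride != 1 || cin != cout) {
    sub$down <- conv_layer(1, cin, cout, stride, 0)
    sub$dbn <- bn_layer(cout)
  }
  list(type = "res", sub = sub)
}

relu_fw <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

bn_fw <- function(ly, x, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2] * d[4]
  xp <- aperm(x, c(1, 2, 4, 3))
  dim(xp) <- c(n, d[3])
  if (train) {
    mu <- colMeans(xp)
    xc <- sweep(xp, 2, mu)
    v <- colMeans(xc * xc)
    ly$state$rm <- (1 - momentum) * ly$state$rm + momentum * mu
    ly$state$rv <- (1 - momentum) * ly$state$rv + momentum * v * n / max(n - 1, 1)
  } else {
    mu <- ly$state$rm
    v <- ly$state$rv
    xc <- sweep(xp, 2, mu)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, ly$par$gamma, `*`), 2, ly$par$beta, `+`)
  dim(y) <- c(d[1], d[2], d[4], d[3])
  list(out = aperm(y, c(1, 2, 4, 3)),
       cache = list(xhat = xhat, istd = istd, d = d, train = train),
       ly = ly)
}

bn_bw <- function(ly, cache, dy) {
  d <- cache$d
  n <- d[1] * d[2] * d[4]
  dyp <- aperm(dy, c(1, 2, 4, 3))
  dim(dyp) <- c(n, d[3])
  dgamma <- colSums(dyp * cache$xhat)
  dbeta <- colSums(dyp)
  dxh <- sweep(dyp, 2, ly$par$gamma, `*`)
  if (cache$train) {
    t1 <- sweep(dxh, 2, colMeans(dxh))
    t2 <- sweep(cache$xhat, 2, colMeans(dxh * cache$xhat), `*`)
    dxp <- sweep(t1 - t2, 2, cache$istd, `*`)
  } else {
    dxp <- sweep(dxh, 2, cache$istd, `*`)
  }
  dim(dxp) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dxp, c(1, 2, 4, 3)),
       grads = list(par = list(gamma = dgamma, beta = dbeta)))
}

res_fw <- function(ly, x, train) {
  c1 <- conv2d_fw_cpp(x, ly$sub$conv1$par$w, ly$sub$conv1$par$b,
                      ly$sub$conv1$stride, ly$sub$conv1$pad, ly$sub$conv1$dil)
  b1 <- bn_fw(ly$sub$bn1, c1, train); ly$sub$bn1 <- b1$ly
  r1 <- relu_fw(b1$out)
  c2 <- conv2d_fw_cpp(r1, ly$sub$conv2$par$w, ly$sub$conv2$par$b,
                      ly$sub$conv2$stride, ly$sub$conv2$pad, ly$sub$conv2$dil)
  b2 <- bn_fw(ly$sub$bn2, c2, train); ly$sub$bn2 <- b2$ly
  if (!is.null(ly$sub$down)) {
    cd <- conv2d_fw_cpp(x, ly$sub$down$par$w, ly$sub$down$par$b,
                        ly$sub$down$stride, ly$sub$down$pad, ly$sub$down$dil)
    bd <- bn_fw(ly$sub$dbn, cd, train); ly$sub$dbn <- bd$ly
    sc <- bd$out
    dcache <- list(cd = cd, bd = bd$cache)
  } else {
    sc <- x
    dcache <- NULL
  }
  pre <- b2$out + sc
  out <- relu_fw(pre)
  list(out = out,
       cache = list(x = x, c1 = c1, b1 = b1$cache, r1 = r1, c2 = c2,
                    b2 = b2$cache, dcache = dcache, mask = pre > 0),
       ly = ly)
}

res_bw <- function(ly, cache, dout) {
  dpre <- dout * cache$mask
  g2 <- bn_bw(ly$sub$bn2, cache$b2, dpre)
  cv2 <- conv2d_bw_cpp(cache$r1, ly$sub$conv2$par$w, g2$dx,
                       ly$sub$conv2$stride, ly$sub$conv2$pad, ly$sub$conv2$dil)
  dr1 <- cv2$gx * (cache$r1 > 0)
  g1 <- bn_bw(ly$sub$bn1, cache$b1, dr1)
  cv1 <- conv2d_bw_cpp(cache$x, ly$sub$conv1$par$w, g1$dx,
                       ly$sub$conv1$stride, ly$sub$conv1$pad, ly$sub$conv1$dil)
  dx <- cv1$gx
  grads <- list(sub = list(
    conv1 = list(par = list(w = cv1$gw, b = cv1$gb)),
    bn1 = g1$grads,
    conv2 = list(par = list(w = cv2$gw, b = cv2$gb)),
    bn2 = g2$grads))
  if (!is.null(ly$sub$down)) {
    gd <- bn_bw(ly$sub$dbn, cache$dcache$bd, dpre)
    cvd <- conv2d_bw_cpp(cache$x, ly$sub$down$par$w, gd$dx,
                         ly$sub$down$stride, ly$sub$down$pad, ly$sub$down$dil)
    dx <- dx + cvd$gx
    grads$sub$down <- list(par = list(w = cvd$gw, b = cvd$gb))
    grads$sub$dbn <- gd$grads
  } else {
    dx <- dx + dpre
  }
  list(dx = dx, grads = grads)
}

layer_fw <- function(ly, x, train) {
  switch(ly$type,
    conv = list(out = conv2d_fw_cpp(x, ly$par$w, ly$par$b,
                                    ly$stride, ly$pad, ly$dil),
                cache = list(x = x), ly = ly),
    bn = bn_fw(ly, x, train),
    relu = list(out = relu_fw(x), cache = list(mask = x > 0), ly = ly),
    maxpool = {
      r <- maxpool_fw_cpp(x, ly$k, ly$stride, ly$pad)
      list(out = r$out, cache = list(argmax = r$argmax, xdim = dim(x)), ly = ly)
    },
    res = res_fw(ly, x, train),
    ca = ca_fw(ly, x, train),
    sa = sa_fw(ly, x, train),
    cbam = cbam_fw(ly, x, train),
    stop("unknown layer type: ", ly$type))
}

layer_bw <- function(ly, cache, dout) {
  switch(ly$type,
    conv = {
      r <- conv2d_bw_cpp(cache$x, ly$par$w, dout, ly$stride, ly$pad, ly$dil)
      list(dx = r$gx, grads = list(par = list(w = r$gw, b = r$gb)))
    },
    bn = bn_bw(ly, cache, dout),
    relu = list(dx = dout * cache$mask, grads = list()),
    maxpool = list(dx = maxpool_bw_cpp(cache$argmax, dout, cache$xdim),
                   grads = list()),
    res = res_bw(ly, cache, dout),
    ca = ca_bw(ly, cache, dout),
    sa = sa_bw(ly, cache, dout),
    cbam = cbam_bw(ly, cache, dout),
    stop("unknown layer type: ", ly$type))
}

net_fw <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    r <- layer_fw(net[[i]], x, train)
    x <- r$out
    caches[[i]] <- r$cache
    net[[i]] <- r$ly
  }
  list(out = x, caches = caches, net = net)
}

net_bw <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    r <- layer_bw(net[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

## ---- parameter flattening (fixed traversal order: par first, then sub) ----

collect_par <- function(ly) {
  out <- list()
  if (!is.null(ly$par)) out <- ly$par
  if (!is.null(ly$sub)) {
    for (s in ly$sub) if (!is.null(s)) out <- c(out, collect_par(s))
  }
  out
}

par_vec <- function(net) {
  unlist(lapply(net, function(ly) lapply(collect_par(ly), as.numeric)),
         use.names = FALSE)
}

# Names (one per scalar-block) and weight-decay mask, aligned with par_vec.
par_info <- function(net) {
  decay_names <- c("w", "w7", "Wz", "Wa", "Wb", "W1", "W2")
  blocks <- unlist(lapply(net, function(ly) {
    p <- collect_par(ly)
    mapply(function(nm, v) rep(nm %in% decay_names, length(v)),
           names(p), p, SIMPLIFY = FALSE)
  }), use.names = FALSE)
  blocks
}

set_par_layer <- function(ly, v, pos) {
  if (!is.null(ly$par)) {
    for (nm in names(ly$par)) {
      n <- length(ly$par[[nm]])
      ly$par[[nm]][] <- v[pos + seq_len(n)]
      pos <- pos + n
    }
  }
  if (!is.null(ly$sub)) {
    for (nm in names(ly$sub)) {
      if (is.null(ly$sub[[nm]])) next
      r <- set_par_layer(ly$sub[[nm]], v, pos)
      ly$sub[[nm]] <- r$ly
      pos <- r$pos
    }
  }
  list(ly = ly, pos = pos)
}

set_par_vec <- function(net, v) {
  pos <- 0
  for (i in seq_along(net)) {
    r <- set_par_layer(net[[i]], v, pos)
    net[[i]] <- r$ly
    pos <- r$pos
  }
  stopifnot(pos == length(v))
  net
}

grad_vec_layer <- function(ly, g) {
  out <- list()
  if (!is.null(ly$par)) {
    for (nm in names(ly$par)) {
      gv <- g$par[[nm]]
      if (is.null(gv)) gv <- numeric(length(ly$par[[nm]]))
      out <- c(out, list(as.numeric(gv)))
    }
  }
  if (!is.null(ly$sub)) {
    for (nm in names(ly$sub)) {
      if (is.null(ly$sub[[nm]])) next
      out <- c(out, list(grad_vec_layer(ly$sub[[nm]], g$sub[[nm]] %||% list())))
    }
  }
  unlist(out, use.names = FALSE)
}

grad_vec <- function(net, grads) {
  unlist(mapply(grad_vec_layer, net, grads, SIMPLIFY = FALSE),
         use.names = FALSE)
}

## ---- Adam ----

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, p, g, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), state = state)
}
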