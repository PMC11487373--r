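# Hybrid attention: a two-branch channel attention (3x3 conv and 3x3 dilated
# conv branches fused by a per-channel two-way softmax) followed by a spatial
# attention gate (L2-normalised pooled maps -> 7x7 conv -> sigmoid).

#' Squeeze dimension of the channel attention bottleneck
#'
#' The channel descriptor of length `C` is compressed by a fully connected
#' layer to `d = max(C / r, L)` units, where `r` is the reduction rate and
#' `L` a floor that stops the bottleneck collapsing for narrow feature maps
#' (default 32).
#'
#' @param C channel count of the feature map.
#' @param r reduction rate (default 16).
#' @param L minimum compressed dimension (default 32).
#' @return integer squeeze dimension.
#' @examples
#' ca_squeeze_dim(64, 16)   # 32
#' ca_squeeze_dim(512, 16)  # 32
#' ca_squeeze_dim(1024, 16) # 64
#' @export
ca_squeeze_dim <- function(C, r = 16, L = 32) {
  stopifnot(C >= 1, r >= 1, L >= 1)
  max(as.integer(floor(C / r)), as.integer(L))
}

# Per-channel two-way softmax over branch logits (C x N matrices).
branch_softmax <- function(la, lb) {
  a <- 1 / (1 + exp(lb - la))
  list(a = a, b = 1 - a)
}

dense_init <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

ca_layer <- function(C, r = 16, L = 32) {
  if (C < 1) stop("channel attention requires at least one channel")
  dz <- ca_squeeze_dim(C, r, L)
  list(type = "ca",
       par = list(Wz = dense_init(dz, C), bz = numeric(dz),
                  Wa = dense_init(C, dz), ba = numeric(C),
                  Wb = dense_init(C, dz), bb = numeric(C)),
       sub = list(conv1 = conv_layer(3, C, C, 1, 1, 1),
                  bn1 = bn_layer(C),
                  conv2 = conv_layer(3, C, C, 1, 2, 2),
                  bn2 = bn_layer(C)),
       C = C, r = r, L = L, dz = dz)
}

ca_fw <- function(ly, x, train) {
  d <- dim(x)
  c1 <- conv2d_fw_cpp(x, ly$sub$conv1$par$w, ly$sub$conv1$par$b, 1L, 1L, 1L)
  b1 <- bn_fw(ly$sub$bn1, c1, train); ly$sub$bn1 <- b1$ly
  u1 <- relu_fw(b1$out)
  c2 <- conv2d_fw_cpp(x, ly$sub$conv2$par$w, ly$sub$conv2$par$b, 1L, 2L, 2L)
  b2 <- bn_fw(ly$sub$bn2, c2, train); ly$sub$bn2 <- b2$ly
  u2 <- relu_fw(b2$out)
  U <- u1 + u2
  # squeeze: global average pool to a channel descriptor s (C x N)
  Up <- aperm(U, c(1, 2, 4, 3))
  dim(Up) <- c(d[1] * d[2], d[4] * d[3])
  s <- matrix(colMeans(Up), nrow = d[4])  # N x C
  s <- t(s)                               # C x N
  z0 <- ly$par$Wz %*% s + ly$par$bz
  z <- relu_fw(z0)
  la <- ly$par$Wa %*% z + ly$par$ba
  lb <- ly$par$Wb %*% z + ly$par$bb
  ab <- branch_softmax(la, lb)
  V <- u1 * bc_chan(ab$a, d) + u2 * bc_chan(ab$b, d)
  list(out = V,
       cache = list(x = x, c1 = c1, b1 = b1$cache, u1 = u1,
                    c2 = c2, b2 = b2$cache, u2 = u2,
                    s = s, z0 = z0, z = z, a = ab$a, d = d),
       ly = ly)
}

ca_bw <- function(ly, cache, dout) {
  d <- cache$d
  a <- cache$a
  ab_ <- bc_chan(a, d)
  # dL/da_c = sum_HW dout * (u1 - u2); a = sigmoid(la - lb)
  du <- dout * (cache$u1 - cache$u2)
  dup <- aperm(du, c(1, 2, 4, 3))
  dim(dup) <- c(d[1] * d[2], d[4] * d[3])
  da <- t(matrix(colSums(dup), nrow = d[4]))  # C x N
  dt <- da * a * (1 - a)
  # back through the two expansion FCs and the shared squeeze
  dz <- crossprod(ly$par$Wa, dt) - crossprod(ly$par$Wb, dt)
  dz0 <- dz * (cache$z0 > 0)
  ds <- crossprod(ly$par$Wz, dz0)             # C x N
  gWa <- tcrossprod(dt, cache$z)
  gba <- rowSums(dt)
  gWb <- tcrossprod(-dt, cache$z)
  gbb <- rowSums(-dt)
  gWz <- tcrossprod(dz0, cache$s)
  gbz <- rowSums(dz0)
  # GAP backward into U, plus the direct V = a u1 + b u2 routes
  dU <- bc_chan(ds / (d[1] * d[2]), d)
  du1 <- ab_ * dout + dU
  du2 <- (1 - ab_) * dout + dU
  du1 <- du1 * (cache$u1 > 0)
  du2 <- du2 * (cache$u2 > 0)
  g1 <- bn_bw(ly$sub$bn1, cache$b1, du1)
  cv1 <- conv2d_bw_cpp(cache$x, ly$sub$conv1$par$w, g1$dx, 1L, 1L, 1L)
  g2 <- bn_bw(ly$sub$bn2, cache$b2, du2)
  cv2 <- conv2d_bw_cpp(cache$x, ly$sub$conv2$par$w, g2$dx, 1L, 2L, 2L)
  list(dx = cv1$gx + cv2$gx,
       grads = list(
         par = list(Wz = gWz, bz = gbz, Wa = gWa, ba = gba, Wb = gWb, bb = gbb),
         sub = list(conv1 = list(par = list(w = cv1$gw, b = cv1$gb)),
                    bn1 = g1$grads,
                    conv2 = list(par = list(w = cv2$gw, b = cv2$gb)),
                    bn2 = g2$grads)))
}

sa_layer <- function() {
  list(type = "sa",
       par = list(w7 = array(stats::rnorm(7 * 7 * 2, 0, sqrt(2 / 98)),
                             c(7, 7, 2, 1)),
                  b7 = 0))
}

# Replicate (edge) padding for the 7x7 attention-map convolution: keeps a
# spatially constant input spatially constant (zero padding would darken the
# borders of the attention map).
pad_idx <- function(n, p) c(rep(1L, p), seq_len(n), rep(n, p))

pad_replicate <- function(x, p) {
  x[pad_idx(dim(x)[1], p), pad_idx(dim(x)[2], p), , , drop = FALSE]
}

# Scatter-add a padded-input gradient back onto the unpadded grid.
unpad_acc <- function(g, H, W, p) {
  d <- dim(g)
  m <- rowsum(matrix(g, nrow = d[1]), pad_idx(H, p))
  a <- aperm(array(m, c(H, d[2], d[3], d[4])), c(2, 1, 3, 4))
  m2 <- rowsum(matrix(a, nrow = d[2]), pad_idx(W, p))
  aperm(array(m2, c(W, H, d[3], d[4])), c(2, 1, 3, 4))
}

# Channel-wise mean and max maps, each (H*W x N), with the max argmax channel.
chan_pool <- function(x) {
  d <- dim(x)
  HW <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(HW, d[3], d[4])
  Fa <- matrix(0, HW, d[4])
  Fm <- matrix(xm[, 1, ], HW, d[4])
  am <- matrix(1L, HW, d[4])
  for (n in seq_len(d[4])) Fa[, n] <- rowMeans(matrix(xm[, , n], HW))
  if (d[3] > 1) {
    for (c in 2:d[3]) {
      xc <- matrix(xm[, c, ], HW, d[4])
      upd <- xc > Fm
      Fm[upd] <- xc[upd]
      am[upd] <- c
    }
  }
  list(Fa = Fa, Fm = Fm, am = am)
}

sa_fw <- function(ly, x, train) {
  d <- dim(x)
  HW <- d[1] * d[2]
  cp <- chan_pool(x)
  na_n <- pmax(sqrt(colSums(cp$Fa^2)), 1e-12)
  nm_n <- pmax(sqrt(colSums(cp$Fm^2)), 1e-12)
  na <- sweep(cp$Fa, 2, na_n, `/`)
  nm <- sweep(cp$Fm, 2, nm_n, `/`)
  P <- array(0, c(d[1], d[2], 2, d[4]))
  P[, , 1, ] <- na
  P[, , 2, ] <- nm
  Pp <- pad_replicate(P, 3L)
  cf <- conv2d_fw_cpp(Pp, ly$par$w7, ly$par$b7, 1L, 0L, 1L)
  M <- 1 / (1 + exp(-cf))
  Mm <- matrix(M, HW, d[4])
  out <- x * bc_spat(Mm, d)
  list(out = out,
       cache = list(x = x, Pp = Pp, Mm = Mm, na = na, nm = nm,
                    na_n = na_n, nm_n = nm_n, am = cp$am, d = d),
       ly = ly)
}

sa_bw <- function(ly, cache, dout) {
  d <- cache$d
  HW <- d[1] * d[2]
  dx <- dout * bc_spat(cache$Mm, d)
  dm <- dout * cache$x
  dim(dm) <- c(HW, d[3], d[4])
  dMm <- matrix(0, HW, d[4])
  for (n in seq_len(d[4])) dMm[, n] <- rowSums(matrix(dm[, , n], HW))
  dcf <- dMm * cache$Mm * (1 - cache$Mm)
  dim(dcf) <- c(d[1], d[2], 1, d[4])
  cb <- conv2d_bw_cpp(cache$Pp, ly$par$w7, dcf, 1L, 0L, 1L)
  dP <- unpad_acc(cb$gx, d[1], d[2], 3L)
  dna <- matrix(dP[, , 1, ], HW, d[4])
  dnm <- matrix(dP[, , 2, ], HW, d[4])
  # L2-normalisation backward: y = F / ||F||  =>  dF = (dy - y <y, dy>) / ||F||
  dFa <- sweep(dna - sweep(cache$na, 2, colSums(dna * cache$na), `*`),
               2, cache$na_n, `/`)
  dFm <- sweep(dnm - sweep(cache$nm, 2, colSums(dnm * cache$nm), `*`),
               2, cache$nm_n, `/`)
  dx <- dx + bc_spat(dFa / d[3], d)
  hwv <- rep(seq_len(HW), d[4])
  nv <- rep(seq_len(d[4]), each = HW)
  lin <- hwv + HW * (as.vector(cache$am) - 1) + HW * d[3] * (nv - 1)
  dx[lin] <- dx[lin] + as.vector(dFm)
  list(dx = dx, grads = list(par = list(w7 = cb$gw, b7 = cb$gb)))
}

# Convolutional block attention (comparison axis): channel gate from a shared
# two-layer MLP over global average- and max-pooled descriptors, then a
# spatial gate without the L2 normalisation step.
cbam_layer <- function(C, r = 16, L = 32) {
  dz <- ca_squeeze_dim(C, r, L)
  list(type = "cbam",
       par = list(W1 = dense_init(dz, C), b1 = numeric(dz),
                  W2 = dense_init(C, dz), b2 = numeric(C),
                  w7 = array(stats::rnorm(7 * 7 * 2, 0, sqrt(2 / 98)),
                             c(7, 7, 2, 1)),
                  b7 = 0),
       C = C, dz = dz)
}

cbam_fw <- function(ly, x, train) {
  d <- dim(x)
  HW <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(HW, d[3], d[4])
  s_avg <- matrix(0, d[3], d[4])
  s_max <- matrix(0, d[3], d[4])
  am <- matrix(0L, d[3], d[4])
  for (n in seq_len(d[4])) {
    plane <- matrix(xm[, , n], HW)
    s_avg[, n] <- colMeans(plane)
    am[, n] <- max.col(t(plane), ties.method = "first")
    s_max[, n] <- plane[cbind(am[, n], seq_len(d[3]))]
  }
  h_avg0 <- ly$par$W1 %*% s_avg + ly$par$b1
  h_max0 <- ly$par$W1 %*% s_max + ly$par$b1
  logits <- ly$par$W2 %*% relu_fw(h_avg0) + ly$par$W2 %*% relu_fw(h_max0) +
    ly$par$b2
  ac <- 1 / (1 + exp(-logits))            # C x N channel gate
  x2 <- x * bc_chan(ac, d)
  cp <- chan_pool(x2)
  P <- array(0, c(d[1], d[2], 2, d[4]))
  P[, , 1, ] <- cp$Fa
  P[, , 2, ] <- cp$Fm
  Pp <- pad_replicate(P, 3L)
  cf <- conv2d_fw_cpp(Pp, ly$par$w7, ly$par$b7, 1L, 0L, 1L)
  Ms <- matrix(1 / (1 + exp(-cf)), HW, d[4])
  out <- x2 * bc_spat(Ms, d)
  list(out = out,
       cache = list(x = x, s_avg = s_avg, s_max = s_max, am = am,
                    h_avg0 = h_avg0, h_max0 = h_max0, ac = ac, x2 = x2,
                    Pp = Pp, Ms = Ms, am_sp = cp$am, d = d),
       ly = ly)
}

cbam_bw <- function(ly, cache, dout) {
  d <- cache$d
  HW <- d[1] * d[2]
  # spatial gate backward
  dx2 <- dout * bc_spat(cache$Ms, d)
  dm <- dout * cache$x2
  dim(dm) <- c(HW, d[3], d[4])
  dMs <- matrix(0, HW, d[4])
  for (n in seq_len(d[4])) dMs[, n] <- rowSums(matrix(dm[, , n], HW))
  dcf <- dMs * cache$Ms * (1 - cache$Ms)
  dim(dcf) <- c(d[1], d[2], 1, d[4])
  cb <- conv2d_bw_cpp(cache$Pp, ly$par$w7, dcf, 1L, 0L, 1L)
  dPs <- unpad_acc(cb$gx, d[1], d[2], 3L)
  dFa <- matrix(dPs[, , 1, ], HW, d[4])
  dFm <- matrix(dPs[, , 2, ], HW, d[4])
  dx2 <- dx2 + bc_spat(dFa / d[3], d)
  hwv <- rep(seq_len(HW), d[4])
  nv <- rep(seq_len(d[4]), each = HW)
  lin <- hwv + HW * (as.vector(cache$am_sp) - 1) + HW * d[3] * (nv - 1)
  dx2[lin] <- dx2[lin] + as.vector(dFm)
  # channel gate backward
  dac_arr <- dx2 * cache$x
  dim(dac_arr) <- c(HW, d[3], d[4])
  dac <- matrix(0, d[3], d[4])
  for (n in seq_len(d[4])) dac[, n] <- colSums(matrix(dac_arr[, , n], HW))
  dx <- dx2 * bc_chan(cache$ac, d)
  dlog <- dac * cache$ac * (1 - cache$ac)
  h_avg <- relu_fw(cache$h_avg0)
  h_max <- relu_fw(cache$h_max0)
  gW2 <- tcrossprod(dlog, h_avg) + tcrossprod(dlog, h_max)
  gb2 <- rowSums(dlog)
  dh_avg <- crossprod(ly$par$W2, dlog) * (cache$h_avg0 > 0)
  dh_max <- crossprod(ly$par$W2, dlog) * (cache$h_max0 > 0)
  gW1 <- tcrossprod(dh_avg, cache$s_avg) + tcrossprod(dh_max, cache$s_max)
  gb1 <- rowSums(dh_avg + dh_max)
  ds_avg <- crossprod(ly$par$W1, dh_avg)
  ds_max <- crossprod(ly$par$W1, dh_max)
  dx <- dx + bc_chan(ds_avg / HW, d)
  cv <- rep(seq_len(d[3]), d[4])
  nv2 <- rep(seq_len(d[4]), each = d[3])
  lin2 <- as.vector(cache$am) + HW * (cv - 1) + HW * d[3] * (nv2 - 1)
  dx[lin2] <- dx[lin2] + as.vector(ds_max)
  list(dx = dx,
       grads = list(par = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                               w7 = cb$gw, b7 = cb$gb)))
}

#' Apply two-branch channel attention to a feature map
#'
#' Two parallel convolution branches (a plain 3x3 and a 3x3 kernel dilated by
#' 2, each followed by batch normalisation and ReLU) produce maps `U1` and
#' `U2`. Their sum is globally average-pooled to a channel descriptor,
#' squeezed to [ca_squeeze_dim()] units, expanded back by two fully connected
#' layers, and a per-channel two-way softmax yields weights `a_c + b_c = 1`.
#' The output is `V_c = a_c U1_c + b_c U2_c`, the same shape as the input.
#'
#' @param x feature map, an `(H, W, C)` or `(H, W, C, N)` numeric array.
#' @param params a layer created by [attention_params()] with
#'   `attention = "ca"`; its channel count must match `x`.
#' @param train logical; use batch statistics (`TRUE`) or running statistics
#'   in the batch-norm branches.
#' @return array of the same shape as `x`, with attribute `"weights"` holding
#'   the `C x N` branch weight matrix `a`.
#' @export
channel_attention <- function(x, params, train = FALSE) {
  x <- as_batch(x)
  if (params$type != "ca") stop("params must be a channel-attention layer")
  if (dim(x)[3] != params$C) stop("channel count mismatch")
  r <- ca_fw(params, x, train)
  structure(r$out, weights = r$cache$a)
}

#' Apply spatial attention to a feature map
#'
#' Channel-wise average and max pooling give two `1 x H x W` maps; each is
#' L2-normalised over its spatial entries, the two are stacked and convolved
#' with a 7x7 kernel (replicate padding 3, so a spatially constant input
#' yields a spatially constant map), and a sigmoid produces the attention map
#' `M_s` with entries strictly in (0, 1). The output is the input scaled
#' position-wise by `M_s`.
#'
#' @inheritParams channel_attention
#' @param params a layer created by [attention_params()] with
#'   `attention = "sa"`.
#' @return array of the same shape as `x`, with attribute `"map"` holding the
#'   `H*W x N` attention map.
#' @export
spatial_attention <- function(x, params, train = FALSE) {
  x <- as_batch(x)
  if (params$type != "sa") stop("params must be a spatial-attention layer")
  r <- sa_fw(params, x, train)
  structure(r$out, map = r$cache$Mm)
}

#' Create attention layer parameters
#'
#' @param attention one of `"ca"` (channel), `"sa"` (spatial), `"cbam"`.
#' @param C channel count the layer operates on (ignored for `"sa"`).
#' @param r,L reduction rate and floor for the squeeze dimension.
#' @param seed integer seed for weight initialisation.
#' @return a layer list usable with [channel_attention()] /
#'   [spatial_attention()].
#' @export
attention_params <- function(attention = c("ca", "sa", "cbam"), C = 64,
                             r = 16, L = 32, seed = 1) {
  attention <- match.arg(attention)
  with_seed(seed, switch(attention,
    ca = ca_layer(C, r, L),
    sa = sa_layer(),
    cbam = cbam_layer(C, r, L)))
}

# Coerce (H,W,C) to a single-sample (H,W,C,1) batch.
as_batch <- function(x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  if (length(dim(x)) != 4) stop("expected an (H, W, C) or (H, W, C, N) array")
  x
}
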