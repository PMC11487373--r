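# Backbone networks. All map an (84, 84, 3) image to an (h, w, d) feature
# map that is read out as m = h*w local descriptors of dimension d; the final
# fully connected and global-average-pooling layers of the classification
# networks are deliberately absent.

# Insert one attention block (or nothing) for a stage of C channels.
attention_block <- function(attention, C, r, L) {
  switch(attention,
    none = list(),
    ca = list(ca_layer(C, r, L)),
    sa = list(sa_layer()),
    ha = list(ca_layer(C, r, L), sa_layer()),
    cbam = list(cbam_layer(C, r, L)),
    stop("unknown attention config: ", attention))
}

# Truncated ResNet18: the last residual stage runs at stride 1 so an 84x84
# input ends at a 6x6x512 map (36 descriptors of dimension 512) instead of
# the 3x3 map a fully strided network would produce.
build_resnet18 <- function(attention, r, L) {
  at <- function(C) attention_block(attention, C, r, L)
  c(list(conv_layer(7, 3, 64, 2, 3), bn_layer(64), relu_layer(),
         maxpool_layer(3, 2, 1),
         res_layer(64, 64, 1), res_layer(64, 64, 1)), at(64),
    list(res_layer(64, 128, 2), res_layer(128, 128, 1)), at(128),
    list(res_layer(128, 256, 2), res_layer(256, 256, 1)), at(256),
    list(res_layer(256, 512, 1), res_layer(512, 512, 1)), at(512))
}

# Small desk-scale backbone: three conv-bn-relu-pool stages ending at a
# 5x5x64 map (25 descriptors of dimension 64), attention after the last pool.
build_reduced <- function(attention, r, L) {
  c(list(conv_layer(3, 3, 16, 2, 1), bn_layer(16), relu_layer(),
         maxpool_layer(2, 2),
         conv_layer(3, 16, 32, 1, 1), bn_layer(32), relu_layer(),
         maxpool_layer(2, 2),
         conv_layer(3, 32, 64, 1, 1), bn_layer(64), relu_layer(),
         maxpool_layer(2, 2)),
    attention_block(attention, 64, r, L))
}

# Classic Conv-64F: four 3x3/64 conv-bn-relu blocks with 2x2 pooling.
build_conv64f <- function(attention, r, L) {
  blk <- function(cin) list(conv_layer(3, cin, 64, 1, 1), bn_layer(64),
                            relu_layer(), maxpool_layer(2, 2))
  c(blk(3), blk(64), blk(64), blk(64),
    attention_block(attention, 64, r, L))
}

#' Construct an (untrained) attention prototypical nearest-neighbour model
#'
#' Builds the embedding network and the metric-head configuration. The model
#' is usable immediately (random weights) and is normally passed to [apnn()]
#' for episodic training.
#'
#' @param backbone `"resnet18"` (the reference embedding: 84x84 input ->
#'   6x6x512 feature map, 36 local descriptors of dimension 512),
#'   `"reduced"` (a small desk-scale network, 5x5x64) or `"conv64f"`.
#' @param attention attention inserted after each backbone stage
#'   (`"resnet18"`) or after the final stage (others): `"ha"` hybrid
#'   channel-then-spatial (default), `"ca"`, `"sa"`, `"cbam"`, or `"none"`.
#' @param r,L reduction rate and floor of the channel-attention squeeze;
#'   see [ca_squeeze_dim()].
#' @param k neighbour count of the image-to-class metric (must not exceed
#'   the descriptor count m).
#' @param distance `"cosine"`, `"euclidean"` or `"manhattan"`.
#' @param image_size input image side in pixels.
#' @param seed seed for weight initialisation.
#' @return an object of class `"apnn"`.
#' @seealso [apnn()], [embed_image()], [predict.apnn()]
#' @export
apnn_model <- function(backbone = c("resnet18", "reduced", "conv64f"),
                       attention = c("ha", "ca", "sa", "cbam", "none"),
                       r = 16, L = 32, k = 3,
                       distance = c("cosine", "euclidean", "manhattan"),
                       image_size = 84, seed = 1) {
  backbone <- match.arg(backbone)
  attention <- match.arg(attention)
  distance <- match.arg(distance)
  net <- with_seed(seed, switch(backbone,
    resnet18 = build_resnet18(attention, r, L),
    reduced = build_reduced(attention, r, L),
    conv64f = build_conv64f(attention, r, L)))
  geom <- embed_geometry(backbone, image_size)
  if (k < 1 || k > geom$m)
    stop("k must lie in [1, m = ", geom$m, "] for this backbone")
  structure(list(net = net,
                 cfg = list(backbone = backbone, attention = attention,
                            r = r, L = L, k = k, distance = distance,
                            image_size = image_size, seed = seed),
                 geom = geom, norm = NULL, history = NULL, trained = FALSE),
            class = "apnn")
}

# Spatial geometry of the descriptor grid for a given backbone/input side.
embed_geometry <- function(backbone, side) {
  dims <- function(s, ops) {
    for (op in ops) s <- op(s)
    s
  }
  half_conv <- function(k, stride, pad) function(s) (s + 2 * pad - k) %/% stride + 1
  s <- switch(backbone,
    resnet18 = dims(side, list(half_conv(7, 2, 3), half_conv(3, 2, 1),
                               half_conv(3, 2, 1), half_conv(3, 2, 1))),
    reduced = dims(side, list(half_conv(3, 2, 1), half_conv(2, 2, 0),
                              half_conv(2, 2, 0), half_conv(2, 2, 0))),
    conv64f = dims(side, list(half_conv(2, 2, 0), half_conv(2, 2, 0),
                              half_conv(2, 2, 0), half_conv(2, 2, 0))))
  d <- switch(backbone, resnet18 = 512L, reduced = 64L, conv64f = 64L)
  list(h = s, w = s, d = d, m = s * s)
}

# Stack images (list of (H,W,3) arrays or a single array) into (H,W,3,N),
# applying the model's per-channel normalisation if present.
prep_batch <- function(model, images) {
  side <- model$cfg$image_size
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  if (is.list(images)) {
    x <- array(0, c(side, side, 3, length(images)))
    for (i in seq_along(images)) {
      im <- images[[i]]
      if (length(dim(im)) != 3 || !all(dim(im)[1:2] == side) || dim(im)[3] != 3)
        stop("image ", i, " is not ", side, "x", side, "x3")
      x[, , , i] <- im
    }
  } else {
    x <- images
    if (length(dim(x)) != 4 || dim(x)[1] != side || dim(x)[3] != 3)
      stop("expected a (", side, ", ", side, ", 3, N) array")
  }
  if (!is.null(model$norm)) {
    for (c in 1:3)
      x[, , c, ] <- (x[, , c, ] - model$norm$mean[c]) / model$norm$sd[c]
  }
  x
}

# Feature map (h,w,d,N) -> list of m x d descriptor matrices.
fmap_to_desc <- function(fm) {
  d <- dim(fm)
  lapply(seq_len(d[4]), function(n) {
    m <- matrix(fm[, , , n], nrow = d[1] * d[2])
    attr(m, "h") <- d[1]
    attr(m, "w") <- d[2]
    m
  })
}

#' Embed images as sets of local descriptors
#'
#' Runs the embedding network in evaluation mode. For the `"resnet18"`
#' backbone an 84x84 image yields h = w = 6 and d = 512, i.e. 36 local
#' descriptors of dimension 512.
#'
#' @param model an [apnn_model()] / [apnn()] object.
#' @param images one `(side, side, 3)` array, a list of them, or a
#'   `(side, side, 3, N)` array.
#' @param batch_size maximum images per forward chunk.
#' @return for a single image, an `m x d` descriptor matrix with attributes
#'   `h` and `w`; for several, a list of such matrices in input order.
#' @export
embed_image <- function(model, images, batch_size = 128) {
  single <- is.array(images) && length(dim(images)) == 3
  x <- prep_batch(model, images)
  N <- dim(x)[4]
  out <- vector("list", N)
  for (start in seq(1, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, N)
    fw <- net_fw(model$net, x[, , , idx, drop = FALSE], train = FALSE)
    out[idx] <- fmap_to_desc(fw$out)
  }
  if (single) out[[1]] else out
}
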