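`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not perturb
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic integer stream splitter: combines any number of integer keys
# into a single seed < 2^31, so per-class / per-instance streams are stable
# no matter how many other streams exist.
mix_seed <- function(...) {
  keys <- as.numeric(c(...))
  h <- 104729
  for (v in keys) {
    v <- abs(v) %% 2147483563
    h <- (h * 69069 + v + 1013904223) %% 2147483563
  }
  as.integer(h %% 2147483562) + 1L
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Row-interpolation matrix for separable bilinear resizing (n_out x n_in).
# Output pixel centres are mapped onto input pixel centres; n_out == n_in
# yields the identity so an 84x84 image round-trips exactly.
interp_mat <- function(n_out, n_in) {
  if (n_out == n_in) return(diag(n_in))
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  lo <- floor(pos)
  w <- pos - lo
  lo <- pmin(pmax(lo, 1), n_in)
  hi <- pmin(lo + 1, n_in)
  M <- matrix(0, n_out, n_in)
  ilo <- cbind(seq_len(n_out), lo)
  ihi <- cbind(seq_len(n_out), hi)
  M[ilo] <- M[ilo] + (1 - w)
  M[ihi] <- M[ihi] + w
  M
}

# Bilinear resize of an (H, W, C) array to (side, side, C).
bilinear_resize <- function(img, side) {
  d <- dim(img)
  Mr <- interp_mat(side, d[1])
  Mc <- t(interp_mat(side, d[2]))
  out <- array(0, c(side, side, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Mr %*% img[, , c] %*% Mc
  out
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Broadcast a (C x N) matrix over the spatial dimensions of a (H,W,C,N) array.
bc_chan <- function(v, d) array(rep(as.vector(v), each = d[1] * d[2]), d)

# Broadcast a (H*W x N) matrix over the channel dimension of a (H,W,C,N) array.
bc_spat <- function(m, d) {
  m <- matrix(m, nrow = d[1] * d[2])
  array(m[, rep(seq_len(d[4]), each = d[3]), drop = FALSE], d)
}
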