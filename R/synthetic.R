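# Procedural generator of fish-like labelled image datasets. The renderings
# are deliberately schematic (ellipse body, stripe bands, fin triangles,
# blob-cluttered background) but reproduce the statistical difficulties of
# underwater species photographs: many visually similar classes, within-class
# appearance jitter, and cluttered scenes.

#' Generate a bank of synthetic species specifications
#'
#' Each class is described by a body aspect ratio, a base hue, a stripe
#' count, a fin scale and a background clutter level. The `difficulty`
#' scalar in \[0, 1) shrinks the inter-class gaps of hue and shape
#' parameters, making classes more alike. Per-class parameters are drawn
#' from independently seeded streams, so enlarging the bank never changes
#' the specs of earlier classes.
#'
#' @param num_classes number of classes (>= 0).
#' @param seed integer seed; the bank is a pure function of
#'   `(num_classes, seed, difficulty, clutter)`.
#' @param difficulty inter-class similarity in \[0, 1): 0 spreads hues over
#'   the full wheel, values near 1 collapse all classes onto one appearance.
#' @param clutter background clutter level in \[0, 1\] shared by all classes.
#' @return a data frame of class `"species_bank"` with columns `class_id`,
#'   `body_aspect`, `hue`, `stripe_count`, `fin_scale`, `clutter_level`.
#' @export
generate_species_bank <- function(num_classes, seed = 1, difficulty = 0.9,
                                  clutter = 0.55) {
  if (length(num_classes) != 1 || is.na(num_classes) || num_classes < 0)
    stop("num_classes must be a non-negative integer")
  num_classes <- as.integer(num_classes)
  stopifnot(difficulty >= 0, difficulty < 1, clutter >= 0, clutter <= 1)
  cols <- c("class_id", "body_aspect", "hue", "stripe_count", "fin_scale",
            "clutter_level")
  if (num_classes == 0) {
    bank <- as.data.frame(stats::setNames(
      list(integer(0), numeric(0), numeric(0), integer(0), numeric(0),
           numeric(0)), cols))
    class(bank) <- c("species_bank", "data.frame")
    return(bank)
  }
  h0 <- with_seed(mix_seed(seed, 11L), stats::runif(1, 0, 360))
  span <- 1 - 0.8 * difficulty
  rows <- lapply(seq_len(num_classes), function(i) {
    # golden-angle hue sequence: well spread for any bank size, and class i's
    # hue does not depend on how many classes follow it
    hue <- (h0 + ((i - 1) * 137.50776) %% 360 * span) %% 360
    with_seed(mix_seed(seed, 1000L + i), {
      aspect <- 2.5 + (stats::runif(1, -1, 1)) * 0.9 * span
      stripes <- sample.int(6L, 1) - 1L
      fin <- 0.35 + stats::runif(1, -1, 1) * 0.2 * span
      data.frame(class_id = i, body_aspect = aspect, hue = hue,
                 stripe_count = stripes, fin_scale = fin,
                 clutter_level = clutter)
    })
  })
  bank <- do.call(rbind, rows)
  class(bank) <- c("species_bank", "data.frame")
  bank
}

# Rotated body-frame coordinates for the pixel grid.
body_frame <- function(side, cx, cy, theta) {
  xs <- matrix(rep(seq_len(side), each = side), side) - cx  # column coord
  ys <- matrix(rep(seq_len(side), side), side) - cy         # row coord
  list(u = cos(theta) * xs + sin(theta) * ys,
       v = -sin(theta) * xs + cos(theta) * ys)
}

#' Render one synthetic fish image
#'
#' Draws an elliptical body with the spec's aspect ratio and hue (jittered by
#' at most 10 degrees per instance), `stripe_count` dark bands across the
#' body, tail and dorsal fin triangles scaled by `fin_scale`, and an eye dot,
#' over a background whose random-blob density follows `clutter_level`.
#' Rendering is a pure function of `(spec, instance_seed)`.
#'
#' @param spec one row of a [generate_species_bank()] data frame (or a list
#'   with the same fields).
#' @param instance_seed integer seed for the per-instance jitter.
#' @param side image side in pixels (default 84).
#' @return a `(side, side, 3)` array with values in \[0, 1\] and attributes
#'   `class_id` and `seed`.
#' @export
render_image <- function(spec, instance_seed = 1, side = 84) {
  spec <- as.list(spec)
  needed <- c("class_id", "body_aspect", "hue", "stripe_count", "fin_scale",
              "clutter_level")
  if (!all(needed %in% names(spec))) stop("spec is missing fields")
  with_seed(mix_seed(314159L, spec$class_id, instance_seed), {
    img <- array(0, c(side, side, 3))
    # water background: vertical gradient, slightly blue
    depth <- (seq_len(side) - 1) / (side - 1)
    img[, , 1] <- matrix(0.16 + 0.05 * depth, side, side)
    img[, , 2] <- matrix(0.26 + 0.06 * depth, side, side)
    img[, , 3] <- matrix(0.34 + 0.08 * depth, side, side)
    # clutter: soft elliptical blobs
    nblob <- round(spec$clutter_level * 40 * stats::runif(1, 0.6, 1.4))
    if (nblob > 0) {
      for (b in seq_len(nblob)) {
        bx <- stats::runif(1, 1, side)
        by <- stats::runif(1, 1, side)
        ba <- stats::runif(1, 2, 9)
        bb <- stats::runif(1, 2, 9)
        bh <- stats::runif(1, 0, 1)
        col <- grDevices::hsv(bh, stats::runif(1, 0.1, 0.45),
                              stats::runif(1, 0.2, 0.6))
        rgbv <- grDevices::col2rgb(col) / 255
        fr <- body_frame(side, bx, by, stats::runif(1, 0, pi))
        mask <- (fr$u / ba)^2 + (fr$v / bb)^2 <= 1
        for (c in 1:3) {
          pl <- img[, , c]
          pl[mask] <- 0.55 * pl[mask] + 0.45 * rgbv[c]
          img[, , c] <- pl
        }
      }
    }
    # body placement jitter: substantial pose/scale variation within a class
    cx <- side / 2 + stats::runif(1, -9, 9)
    cy <- side / 2 + stats::runif(1, -9, 9)
    theta <- stats::runif(1, -0.45, 0.45)
    a <- side / 3 * stats::runif(1, 0.72, 1.28)
    b <- a / spec$body_aspect
    hue <- (spec$hue + stats::runif(1, -10, 10)) %% 360
    sat <- min(max(0.65 + stats::runif(1, -0.08, 0.08), 0), 1)
    val <- min(max(0.75 + stats::runif(1, -0.08, 0.08), 0), 1)
    body_rgb <- grDevices::col2rgb(grDevices::hsv(hue / 360, sat, val)) / 255
    fin_rgb <- body_rgb * 0.7
    fr <- body_frame(side, cx, cy, theta)
    u <- fr$u
    v <- fr$v
    body <- (u / a)^2 + (v / b)^2 <= 1
    # tail fin: triangle narrowing away from the rear of the body
    fl <- max(spec$fin_scale, 0.05) * a
    tail <- u >= -(a + fl) & u <= -0.85 * a &
      abs(v) <= 1.1 * b * (u + a + fl) / fl
    # dorsal fin: triangle on the back
    dh <- 1.6 * max(spec$fin_scale, 0.05) * b
    dorsal <- v >= 0.75 * b & v <= 0.75 * b + dh &
      abs(u) <= 0.3 * a * (1 - (v - 0.75 * b) / dh)
    for (c in 1:3) {
      pl <- img[, , c]
      pl[tail | dorsal] <- fin_rgb[c]
      pl[body] <- body_rgb[c]
      img[, , c] <- pl
    }
    # stripes: dark bands across the body, evenly spaced along its axis
    if (spec$stripe_count > 0) {
      tt <- (u / a + 1) / 2  # 0..1 along the body
      ph <- (tt * spec$stripe_count) %% 1
      stripes <- body & ph < 0.35 & tt > 0.05 & tt < 0.95
      for (c in 1:3) {
        pl <- img[, , c]
        pl[stripes] <- pl[stripes] * 0.45
        img[, , c] <- pl
      }
    }
    # eye near the head
    eye <- ((u - 0.7 * a) / 2.2)^2 + (v / 2.2)^2 <= 1
    for (c in 1:3) {
      pl <- img[, , c]
      pl[eye] <- 0.05
      img[, , c] <- pl
    }
    img <- clamp01(img)
    attr(img, "class_id") <- spec$class_id
    attr(img, "seed") <- instance_seed
    img
  })
}

#' Write a synthetic dataset to disk in class-per-directory layout
#'
#' Renders `num_classes * per_class` PNG images under
#' `out_dir/class_<id>/<idx>.png` and returns the corresponding
#' [index_folder()] dataset index. Rebuilding with the same arguments
#' reproduces byte-identical files.
#'
#' @inheritParams generate_species_bank
#' @param per_class images rendered per class.
#' @param out_dir output directory (created if needed).
#' @param manifest also write a `manifest.csv` of `path,label` pairs.
#' @param side image side in pixels.
#' @return a `dataset_index` covering the generated files.
#' @export
build_dataset <- function(num_classes, per_class, out_dir, seed = 1,
                          difficulty = 0.9, clutter = 0.55, side = 84,
                          manifest = FALSE) {
  bank <- generate_species_bank(num_classes, seed, difficulty, clutter)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  for (i in seq_len(num_classes)) {
    cdir <- file.path(out_dir, sprintf("class_%03d", bank$class_id[i]))
    if (!dir.exists(cdir) && !dir.create(cdir, showWarnings = FALSE))
      stop("cannot create class directory: ", cdir)
    for (j in seq_len(per_class)) {
      img <- render_image(bank[i, ], instance_seed = mix_seed(seed, i, j),
                          side = side)
      png::writePNG(img, file.path(cdir, sprintf("%03d.png", j)))
    }
  }
  idx <- index_folder(out_dir)
  if (manifest) {
    utils::write.csv(
      data.frame(path = idx$samples$path,
                 label = idx$classes[idx$samples$class_id]),
      file.path(out_dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
  }
  idx
}
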