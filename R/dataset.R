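# Dataset indexing, class-disjoint splitting and K-way N-shot episode
# sampling. Few-shot evaluation requires novel classes, so splits partition
# the *classes*, never the images.

#' Construct a dataset index
#'
#' @param paths character vector of image paths.
#' @param labels class label (character) per path.
#' @param split_tag one of `"train"`, `"val"`, `"test"`, `"unsplit"`.
#' @param check verify that every path exists.
#' @return an object of class `"dataset_index"`: list with `samples`
#'   (data frame `path`, `class_id`), `classes` (ordered class names) and
#'   `split_tag`.
#' @export
dataset_index <- function(paths, labels, split_tag = "unsplit", check = TRUE) {
  stopifnot(length(paths) == length(labels))
  if (length(paths) == 0) stop("empty dataset: no samples")
  if (check && !all(file.exists(paths)))
    stop("missing files: ", paste(utils::head(paths[!file.exists(paths)], 3),
                                  collapse = ", "))
  classes <- sort(unique(as.character(labels)), method = "radix")
  structure(list(samples = data.frame(
                   path = as.character(paths),
                   class_id = match(as.character(labels), classes)),
                 classes = classes,
                 split_tag = match.arg(split_tag,
                                       c("unsplit", "train", "val", "test"))),
            class = "dataset_index")
}

#' @export
print.dataset_index <- function(x, ...) {
  cat("<dataset_index> ", nrow(x$samples), " samples, ",
      length(x$classes), " classes [", x$split_tag, "]\n", sep = "")
  invisible(x)
}

#' Index a class-per-directory image folder
#'
#' Every sub-directory of `root` is a class; classes are ordered
#' lexicographically so re-indexing is stable. Empty class directories are
#' excluded with a warning.
#'
#' @param root dataset root directory.
#' @return a [dataset_index()].
#' @export
index_folder <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  dirs <- sort(list.dirs(root, recursive = FALSE), method = "radix")
  if (length(dirs) == 0) stop("empty dataset: no class directories in ", root)
  paths <- character(0)
  labels <- character(0)
  for (d in dirs) {
    fs <- sort(list.files(d, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                          full.names = TRUE), method = "radix")
    if (length(fs) == 0) {
      warning("class directory ", basename(d), " has no images; excluded")
      next
    }
    paths <- c(paths, fs)
    labels <- c(labels, rep(basename(d), length(fs)))
  }
  if (length(paths) == 0) stop("empty dataset: no images under ", root)
  dataset_index(paths, labels, check = FALSE)
}

# Keep only the named classes (re-numbering class ids).
subset_classes <- function(index, keep, split_tag) {
  sel <- index$samples$class_id %in% match(keep, index$classes)
  dataset_index(index$samples$path[sel],
                index$classes[index$samples$class_id[sel]],
                split_tag = split_tag, check = FALSE)
}

#' Split a dataset into class-disjoint train/val/test parts
#'
#' Classes (not images) are partitioned, proportionally to `ratios` after
#' normalisation, using largest-remainder apportionment so the class counts
#' sum exactly. Ratios such as `c(7, 2, 3)` or `c(640, 160, 200)` are
#' treated as proportions.
#'
#' @param index a [dataset_index()].
#' @param ratios positive length-3 numeric vector (train, val, test).
#' @param seed integer seed for the class shuffle.
#' @return named list of three `dataset_index` objects (`train`, `val`,
#'   `test`); their class sets partition the original.
#' @export
split_classes <- function(index, ratios = c(7, 2, 3), seed = 1) {
  stopifnot(inherits(index, "dataset_index"), length(ratios) == 3,
            all(ratios > 0))
  nc <- length(index$classes)
  q <- nc * ratios / sum(ratios)
  base <- floor(q)
  rem <- nc - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  if (any(base < 1))
    stop("ratios leave a split part with zero classes (", nc, " classes)")
  perm <- with_seed(seed, sample(index$classes))
  parts <- split(perm, rep(c("train", "val", "test"), times = base))
  list(train = subset_classes(index, parts$train, "train"),
       val = subset_classes(index, parts$val, "val"),
       test = subset_classes(index, parts$test, "test"))
}

#' Save / load a split assignment
#'
#' Records which class went to which part as JSON for reproducibility.
#' @param splits result of [split_classes()].
#' @param path JSON file path.
#' @export
write_split <- function(splits, path) {
  jsonlite::write_json(lapply(splits, function(s) s$classes), path,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Episode specification
#'
#' @param ways number of classes K per episode (>= 1).
#' @param shots support images N per class (>= 1).
#' @param queries query images M per class (>= 0).
#' @return a list of class `"episode_spec"`.
#' @export
episode_spec <- function(ways = 5, shots = 5, queries = 15) {
  stopifnot(ways >= 1, shots >= 1, queries >= 0)
  structure(list(ways = as.integer(ways), shots = as.integer(shots),
                 queries = as.integer(queries)), class = "episode_spec")
}

#' Sample one K-way N-shot episode
#'
#' Draws `ways` classes without replacement, then `shots + queries` distinct
#' images per class, partitioned into support and query sets (so the two
#' never share a file). Episode-local labels `0..K-1` follow the order in
#' which classes were drawn; global class names are retained.
#'
#' @param index a [dataset_index()].
#' @param spec an [episode_spec()].
#' @param seed integer seed, or `NULL` to consume the current RNG stream.
#' @return an object of class `"episode"`: list with data frames `support`
#'   and `query` (columns `path`, `label`, `class`) and the drawn `classes`.
#' @export
sample_episode <- function(index, spec = episode_spec(), seed = NULL) {
  stopifnot(inherits(index, "dataset_index"), inherits(spec, "episode_spec"))
  counts <- tabulate(index$samples$class_id, length(index$classes))
  if (spec$ways > length(index$classes))
    stop("episode needs ", spec$ways, " classes but index has ",
         length(index$classes))
  if (min(counts) < spec$shots + spec$queries)
    stop("a class has fewer than shots + queries = ",
         spec$shots + spec$queries, " images")
  draw <- function() {
    cls <- sample(seq_along(index$classes), spec$ways)
    sup <- vector("list", spec$ways)
    qry <- vector("list", spec$ways)
    for (i in seq_along(cls)) {
      pool <- index$samples$path[index$samples$class_id == cls[i]]
      sel <- sample(pool, spec$shots + spec$queries)
      sup[[i]] <- data.frame(path = sel[seq_len(spec$shots)],
                             label = i - 1L,
                             class = index$classes[cls[i]])
      if (spec$queries > 0)
        qry[[i]] <- data.frame(path = sel[spec$shots + seq_len(spec$queries)],
                               label = i - 1L,
                               class = index$classes[cls[i]])
    }
    structure(list(support = do.call(rbind, sup),
                   query = if (spec$queries > 0) do.call(rbind, qry)
                           else data.frame(path = character(0),
                                           label = integer(0),
                                           class = character(0)),
                   classes = index$classes[cls], spec = spec),
              class = "episode")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' @export
print.episode <- function(x, ...) {
  cat("<episode> ", x$spec$ways, "-way ", x$spec$shots, "-shot, ",
      x$spec$queries, " queries/class\n", sep = "")
  invisible(x)
}

#' Load an image as an 84x84x3 array
#'
#' Reads a PNG (or, if the `EBImage` package is available, JPEG) file,
#' replicates greyscale to three channels, drops any alpha channel, and
#' bilinearly resizes to `side x side`. Values are in \[0, 1\].
#'
#' @param path image file.
#' @param side output side in pixels.
#' @return a `(side, side, 3)` numeric array.
#' @export
load_image <- function(path, side = 84) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    tryCatch(png::readPNG(path),
             error = function(e) stop("cannot read image: ", path, " (",
                                      conditionMessage(e), ")"))
  } else if (requireNamespace("EBImage", quietly = TRUE)) {
    aperm(array(EBImage::imageData(EBImage::readImage(path)),
                dim = c(dim(EBImage::readImage(path))[1:2], 3)), c(2, 1, 3))
  } else {
    stop("cannot read image: ", path, " (only PNG supported without EBImage)")
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 2) img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3]
  clamp01(bilinear_resize(img, side))
}
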