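#' @export
print.apnn <- function(x, ...) {
  cat("Attention prototypical nearest-neighbour model\n")
  cat("  backbone: ", x$cfg$backbone, " (descriptors: ", x$geom$m, " x ",
      x$geom$d, ", grid ", x$geom$h, "x", x$geom$w, ")\n", sep = "")
  cat("  attention:", x$cfg$attention, "  metric: k =", x$cfg$k,
      x$cfg$distance, "\n")
  cat("  parameters:", format(length(par_vec(x$net)), big.mark = ","), "\n")
  if (x$trained) {
    h <- x$history
    cat(sprintf("  trained: %d epochs, final loss %.4f", nrow(h),
                h$loss[nrow(h)]))
    if (!all(is.na(h$val_acc)))
      cat(sprintf(", best val acc %.3f (epoch %d)",
                  max(h$val_acc, na.rm = TRUE), x$best_epoch))
    cat("\n")
  } else cat("  untrained (random initialisation)\n")
  invisible(x)
}

#' @export
summary.apnn <- function(object, ...) {
  structure(list(cfg = object$cfg, geom = object$geom,
                 n_par = length(par_vec(object$net)),
                 trained = object$trained, history = object$history),
            class = "summary.apnn")
}

#' @export
print.summary.apnn <- function(x, ...) {
  cat("Model configuration\n")
  for (nm in names(x$cfg)) cat("  ", nm, ": ", format(x$cfg[[nm]]), "\n",
                               sep = "")
  cat("Descriptor geometry: m =", x$geom$m, "of dimension", x$geom$d, "\n")
  cat("Trainable parameters:", x$n_par, "\n")
  if (!is.null(x$history)) {
    cat("Training history (last rows):\n")
    print(utils::tail(x$history, 5))
  }
  invisible(x)
}

#' @export
coef.apnn <- function(object, ...) {
  lapply(seq_along(object$net), function(i) collect_par(object$net[[i]]))
}

#' Predict episode-local labels for query images
#'
#' Embeds the episode's support and query images, forms class prototypes,
#' and classifies each query with the k-nearest-descriptor softmax.
#'
#' @param object an `"apnn"` model.
#' @param episode an [sample_episode()] result (paths must be readable).
#' @param type `"class"` for episode-local labels `0..K-1`, `"prob"` for
#'   the query-by-class probability matrix, `"score"` for raw scores.
#' @param ... unused.
#' @return labels, or a matrix with one row per query.
#' @export
predict.apnn <- function(object, episode,
                         type = c("class", "prob", "score"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(episode, "episode"))
  spec <- episode$spec
  paths <- c(episode$support$path, episode$query$path)
  imgs <- lapply(paths, load_image, side = object$cfg$image_size)
  desc <- embed_image(object, imgs)
  ns <- spec$ways * spec$shots
  protos <- compute_prototypes(split(desc[seq_len(ns)],
                                     rep(seq_len(spec$ways),
                                         each = spec$shots)))
  qd <- desc[-seq_len(ns)]
  sc <- t(vapply(qd, function(Q)
    vapply(protos, function(P)
      knn_class_score(Q, P, object$cfg$k, object$cfg$distance), numeric(1)),
    numeric(spec$ways)))
  colnames(sc) <- episode$classes
  switch(type,
    class = max.col(sc, ties.method = "first") - 1L,
    prob = t(apply(sc, 1, softmax)),
    score = sc)
}

#' Plot the training history of a fitted model
#'
#' @param x a trained `"apnn"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.apnn <- function(x, ...) {
  if (is.null(x$history) || nrow(x$history) == 0)
    stop("model has no training history")
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "episode loss", main = "training loss", ...)
  if (!all(is.na(h$val_acc)))
    graphics::plot(h$epoch, h$val_acc, type = "b", xlab = "epoch",
                   ylab = "validation accuracy", main = "validation", ...)
  else
    graphics::plot(h$epoch, h$train_acc, type = "b", xlab = "epoch",
                   ylab = "train episode accuracy", main = "training", ...)
  invisible(x)
}
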