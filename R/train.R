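# Episodic training (Adam) and the repeated-evaluation protocol.

#' Training and evaluation configuration
#'
#' Defaults follow the reference protocol: Adam with initial learning rate
#' 0.001 decayed by `gamma = 0.5` every 20 epochs, weight decay 5e-4,
#' 84-pixel inputs, 100 training epochs of 600 episodes, and 20 test epochs
#' of 600 episodes each. `batch_size` bounds the number of images forwarded
#' per device batch within an episode. Desk-scale runs override
#' `train_epoch`/`train_episode` downwards.
#'
#' @param lr initial Adam learning rate.
#' @param gamma multiplicative learning-rate decay applied every 20 epochs.
#' @param weight_decay L2 penalty on convolution / dense weights.
#' @param batch_size maximum images per forward chunk.
#' @param image_size input image side in pixels.
#' @param train_epoch,test_epoch number of training epochs and of evaluation
#'   repeats.
#' @param train_episode,test_episode episodes per training epoch / per
#'   evaluation repeat.
#' @param ways,shots,queries episode shape (K-way N-shot, M queries per
#'   class).
#' @param val_episode validation episodes per epoch.
#' @param seed master seed for episode sampling and initialisation.
#' @return a list of class `"apnn_config"`.
#' @export
apnn_config <- function(lr = 0.001, gamma = 0.5, weight_decay = 5e-4,
                        batch_size = 128, image_size = 84,
                        train_epoch = 100, test_epoch = 20,
                        train_episode = 600, test_episode = 600,
                        ways = 5, shots = 5, queries = 15,
                        val_episode = 30, seed = 1) {
  cfg <- list(lr = lr, gamma = gamma, weight_decay = weight_decay,
              batch_size = batch_size, image_size = image_size,
              train_epoch = train_epoch, test_epoch = test_epoch,
              train_episode = train_episode, test_episode = test_episode,
              ways = ways, shots = shots, queries = queries,
              val_episode = val_episode, seed = seed)
  stopifnot(lr >= 0, gamma > 0, weight_decay >= 0, batch_size >= 1,
            image_size >= 1, train_epoch >= 1, test_epoch >= 1,
            train_episode >= 1, test_episode >= 1, ways >= 1, shots >= 1,
            queries >= 0)
  structure(cfg, class = "apnn_config")
}

#' Top-1 classification accuracy
#'
#' The fraction T / (T + F) of correctly predicted samples.
#'
#' @param predicted,true equal-length label vectors (length >= 1).
#' @return fraction in \[0, 1\].
#' @export
accuracy <- function(predicted, true) {
  if (length(predicted) == 0 || length(predicted) != length(true))
    stop("predicted and true labels must have equal positive length")
  mean(predicted == true)
}

# In-memory image cache for an index (path -> normalised-size array).
preload_images <- function(indexes, side) {
  cache <- new.env(parent = emptyenv())
  for (idx in indexes) {
    if (is.null(idx)) next
    for (p in unique(idx$samples$path))
      if (is.null(cache[[p]])) cache[[p]] <- load_image(p, side)
  }
  cache
}

channel_stats <- function(cache, index) {
  sums <- numeric(3)
  sq <- numeric(3)
  npix <- 0
  for (p in unique(index$samples$path)) {
    im <- cache[[p]]
    npix <- npix + dim(im)[1] * dim(im)[2]
    for (c in 1:3) {
      sums[c] <- sums[c] + sum(im[, , c])
      sq[c] <- sq[c] + sum(im[, , c]^2)
    }
  }
  mu <- sums / npix
  list(mean = mu, sd = pmax(sqrt(sq / npix - mu^2), 1e-6))
}

fetch_batch <- function(cache, paths, side) {
  x <- array(0, c(side, side, 3, length(paths)))
  for (i in seq_along(paths)) x[, , , i] <- cache[[paths[i]]]
  x
}

# Loss, episode accuracy and descriptor gradients for one episode.
# desc: list of m x d matrices, support images first (grouped by class,
# shots consecutive), then queries. Returns ddesc aligned with desc.
episode_grad <- function(desc, ways, shots, labels, k, distance,
                         want_grad = TRUE) {
  ns <- ways * shots
  sup <- desc[seq_len(ns)]
  qry <- desc[-seq_len(ns)]
  m <- nrow(sup[[1]])
  d <- ncol(sup[[1]])
  protos <- lapply(seq_len(ways), function(c)
    Reduce(`+`, sup[(c - 1) * shots + seq_len(shots)]) / shots)
  nq <- length(qry)
  dsup <- lapply(seq_len(ns), function(i) matrix(0, m, d))
  dqry <- lapply(seq_len(nq), function(i) matrix(0, m, d))
  loss <- 0
  correct <- 0
  for (q in seq_len(nq)) {
    Q <- qry[[q]]
    sc <- numeric(ways)
    sel <- vector("list", ways)
    Sm <- vector("list", ways)
    for (c in seq_len(ways)) {
      S <- pair_scores(Q, protos[[c]], distance, warn = FALSE)
      idx <- topk_idx(S, k)
      sel[[c]] <- idx
      Sm[[c]] <- S
      sc[c] <- sum(S[cbind(rep(seq_len(m), k), as.vector(idx))])
    }
    p <- softmax(sc)
    t1 <- labels[q] + 1L
    loss <- loss + (-log(max(p[t1], 1e-300)))
    if (which.max(sc) == t1) correct <- correct + 1
    if (!want_grad) next
    dsc <- p
    dsc[t1] <- dsc[t1] - 1
    dsc <- dsc / nq
    for (c in seq_len(ways)) {
      w <- dsc[c]
      if (w == 0) next
      iv <- rep(seq_len(m), k)
      jv <- as.vector(sel[[c]])
      P <- protos[[c]]
      if (distance == "cosine") {
        qn <- pmax(row_norms(Q), 1e-12)
        pn <- pmax(row_norms(P), 1e-12)
        Qn <- Q / qn
        Pn <- P / pn
        sv <- Sm[[c]][cbind(iv, jv)]
        gq <- (Pn[jv, , drop = FALSE] - sv * Qn[iv, , drop = FALSE]) / qn[iv]
        gp <- (Qn[iv, , drop = FALSE] - sv * Pn[jv, , drop = FALSE]) / pn[jv]
      } else if (distance == "euclidean") {
        diff <- Q[iv, , drop = FALSE] - P[jv, , drop = FALSE]
        dist <- pmax(-Sm[[c]][cbind(iv, jv)], 1e-12)
        gq <- -diff / dist
        gp <- diff / dist
      } else {
        diff <- Q[iv, , drop = FALSE] - P[jv, , drop = FALSE]
        gq <- -sign(diff)
        gp <- sign(diff)
      }
      gq_acc <- rowsum(w * gq, iv)
      dqry[[q]][as.integer(rownames(gq_acc)), ] <-
        dqry[[q]][as.integer(rownames(gq_acc)), ] + gq_acc
      gp_acc <- rowsum(w * gp, jv)
      rows <- as.integer(rownames(gp_acc))
      for (s in seq_len(shots)) {
        i <- (c - 1) * shots + s
        dsup[[i]][rows, ] <- dsup[[i]][rows, ] + gp_acc / shots
      }
    }
  }
  list(loss = loss / max(nq, 1), acc = correct / max(nq, 1),
       ddesc = c(dsup, dqry))
}

# Descriptor gradients -> feature-map gradient array (h,w,d,N).
desc_to_fmap <- function(ddesc, h, w, d) {
  N <- length(ddesc)
  g <- array(0, c(h, w, d, N))
  for (n in seq_len(N)) g[, , , n] <- array(ddesc[[n]], c(h, w, d))
  g
}

#' Train an attention prototypical nearest-neighbour classifier
#'
#' Episodic training: each iteration samples a K-way N-shot episode from the
#' class-disjoint training index, embeds support and query images, scores
#' queries against class prototypes with the k-nearest-descriptor metric,
#' and takes one Adam step on the episodic cross-entropy loss. After each
#' epoch the model is scored on validation episodes; the returned model
#' carries the parameters of the best validation epoch (ties favour the
#' earlier epoch).
#'
#' @param train a [dataset_index()] of training classes.
#' @param val optional [dataset_index()] of validation classes
#'   (class-disjoint from `train`); if `NULL`, the final epoch is kept.
#' @param model an [apnn_model()]; defaults to the reference ResNet18
#'   hybrid-attention embedding.
#' @param config an [apnn_config()].
#' @param verbose print per-epoch progress.
#' @return the trained `"apnn"` object, with a `history` data frame
#'   (epoch, mean episode loss, training episode accuracy, validation
#'   accuracy) and the normalisation statistics of the training split.
#' @export
apnn <- function(train, val = NULL, model = NULL, config = apnn_config(),
                 verbose = FALSE) {
  stopifnot(inherits(train, "dataset_index"))
  if (is.null(model))
    model <- apnn_model(image_size = config$image_size,
                        seed = mix_seed(config$seed, 77L))
  spec <- episode_spec(config$ways, config$shots, config$queries)
  counts <- tabulate(train$samples$class_id, length(train$classes))
  if (spec$ways > length(train$classes) ||
      min(counts) < spec$shots + spec$queries)
    stop("episode spec unsatisfiable by the training index")
  if (!is.null(val) && length(intersect(train$classes, val$classes)) > 0)
    stop("train and val must be class-disjoint")
  cache <- preload_images(list(train, val), config$image_size)
  model$norm <- channel_stats(cache, train)
  model$cfg$k <- min(model$cfg$k, model$geom$m)

  net <- model$net
  pv <- par_vec(net)
  decay_mask <- par_info(net)
  opt <- adam_init(length(pv))
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     train_acc = numeric(0), val_acc = numeric(0))
  best <- list(acc = -Inf, net = net, epoch = 0)
  set.seed(config$seed)
  for (epoch in seq_len(config$train_epoch)) {
    lr_e <- config$lr * config$gamma^((epoch - 1) %/% 20)
    ep_loss <- numeric(config$train_episode)
    ep_acc <- numeric(config$train_episode)
    for (e in seq_len(config$train_episode)) {
      epi <- sample_episode(train, spec, seed = NULL)
      paths <- c(epi$support$path, epi$query$path)
      x <- fetch_batch(cache, paths, config$image_size)
      for (c in 1:3)
        x[, , c, ] <- (x[, , c, ] - model$norm$mean[c]) / model$norm$sd[c]
      fw <- net_fw(net, x, train = TRUE)
      net <- fw$net
      desc <- fmap_to_desc(fw$out)
      g <- episode_grad(desc, spec$ways, spec$shots, epi$query$label,
                        model$cfg$k, model$cfg$distance)
      ep_loss[e] <- g$loss
      ep_acc[e] <- g$acc
      dfm <- desc_to_fmap(g$ddesc, model$geom$h, model$geom$w, model$geom$d)
      bw <- net_bw(net, fw$caches, dfm)
      gv <- grad_vec(net, bw$grads)
      gv <- gv + config$weight_decay * pv * decay_mask
      st <- adam_step(opt, pv, gv, lr_e)
      opt <- st$state
      pv <- st$p
      net <- set_par_vec(net, pv)
    }
    model$net <- net
    vacc <- NA_real_
    if (!is.null(val)) {
      vacc <- mean(vapply(seq_len(config$val_episode), function(i) {
        run_episode(model, val, spec, cache)
      }, numeric(1)))
      if (vacc > best$acc) best <- list(acc = vacc, net = net, epoch = epoch)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(ep_loss),
                                   train_acc = mean(ep_acc), val_acc = vacc))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f train acc %.3f val acc %s",
                      epoch, mean(ep_loss), mean(ep_acc),
                      ifelse(is.na(vacc), "-", sprintf("%.3f", vacc))))
  }
  if (!is.null(val) && is.finite(best$acc)) model$net <- best$net
  model$history <- hist
  model$trained <- TRUE
  model$best_epoch <- if (!is.null(val)) best$epoch else config$train_epoch
  model
}

# One evaluation episode: returns top-1 accuracy. Consumes the RNG stream.
run_episode <- function(model, index, spec, cache = NULL) {
  epi <- sample_episode(index, spec, seed = NULL)
  paths <- c(epi$support$path, epi$query$path)
  x <- if (is.null(cache)) {
    imgs <- lapply(paths, load_image, side = model$cfg$image_size)
    arr <- array(0, c(model$cfg$image_size, model$cfg$image_size, 3,
                      length(imgs)))
    for (i in seq_along(imgs)) arr[, , , i] <- imgs[[i]]
    arr
  } else fetch_batch(cache, paths, model$cfg$image_size)
  if (!is.null(model$norm))
    for (c in 1:3)
      x[, , c, ] <- (x[, , c, ] - model$norm$mean[c]) / model$norm$sd[c]
  fw <- net_fw(model$net, x, train = FALSE)
  desc <- fmap_to_desc(fw$out)
  g <- episode_grad(desc, spec$ways, spec$shots, epi$query$label,
                    model$cfg$k, model$cfg$distance, want_grad = FALSE)
  g$acc
}

#' Evaluate a model (or predictor) under the repeated-episode protocol
#'
#' Samples `episodes` episodes per repeat for `repeats` repeats, records the
#' top-1 accuracy of each episode, and reports the mean accuracy (percent)
#' with a 95 percent confidence half-width `1.96 * sd / sqrt(total)` over
#' all episodes.
#'
#' @param object an `"apnn"` model, or a function `f(episode)` returning
#'   predicted episode-local labels (`0..K-1`) for the episode's queries
#'   (used e.g. for chance-level baselines).
#' @param index a [dataset_index()] of evaluation classes.
#' @param spec an [episode_spec()].
#' @param episodes episodes per repeat.
#' @param repeats number of repeats.
#' @param seed integer seed.
#' @param cache optional preloaded image cache (internal use).
#' @param ... unused.
#' @return an object of class `"apnn_eval"`: list with `mean_accuracy`
#'   (percent), `ci_halfwidth` (percent), `episodes_evaluated`, and the
#'   per-episode accuracy vector `per_episode`.
#' @export
evaluate <- function(object, ...) UseMethod("evaluate")

#' @rdname evaluate
#' @export
evaluate.apnn <- function(object, index, spec = episode_spec(),
                          episodes = 600, repeats = 20, seed = 1,
                          cache = NULL, ...) {
  stopifnot(inherits(index, "dataset_index"))
  if (spec$ways > length(index$classes))
    stop("too few classes (", length(index$classes), ") for ", spec$ways,
         "-way evaluation")
  if (is.null(cache))
    cache <- preload_images(list(index), object$cfg$image_size)
  acc <- with_seed(seed, vapply(seq_len(episodes * repeats), function(i)
    run_episode(object, index, spec, cache), numeric(1)))
  eval_summary(acc)
}

#' @rdname evaluate
#' @export
evaluate.function <- function(object, index, spec = episode_spec(),
                              episodes = 600, repeats = 20, seed = 1, ...) {
  stopifnot(inherits(index, "dataset_index"))
  if (spec$ways > length(index$classes))
    stop("too few classes for ", spec$ways, "-way evaluation")
  acc <- with_seed(seed, vapply(seq_len(episodes * repeats), function(i) {
    epi <- sample_episode(index, spec, seed = NULL)
    accuracy(object(epi), epi$query$label)
  }, numeric(1)))
  eval_summary(acc)
}

eval_summary <- function(acc) {
  n <- length(acc)
  sdv <- if (n > 1) stats::sd(acc) else 0
  structure(list(mean_accuracy = 100 * mean(acc),
                 ci_halfwidth = 100 * 1.96 * sdv / sqrt(n),
                 episodes_evaluated = n,
                 per_episode = acc),
            class = "apnn_eval")
}

#' @export
print.apnn_eval <- function(x, ...) {
  cat(sprintf("episode accuracy: %.3f%% +/- %.3f%% (95%% CI, %d episodes)\n",
              x$mean_accuracy, x$ci_halfwidth, x$episodes_evaluated))
  invisible(x)
}

#' Descriptor-norm activation map
#'
#' Saliency of each spatial position of the embedding, computed as the L2
#' norm of the local descriptor at that position after attention, min-max
#' normalised to \[0, 1\] (a constant map is returned as all 0.5), and
#' bilinearly upsampled to the input size for overlay. The pre-upsampling
#' grid (h x w, e.g. 6x6 for the ResNet18 embedding of an 84-pixel image)
#' is attached as attribute `"grid"`.
#'
#' @param model an [apnn_model()] / [apnn()] object.
#' @param image a `(side, side, 3)` image array.
#' @return a `side x side` matrix of class `"apnn_cam"` with values in
#'   \[0, 1\].
#' @export
activation_map <- function(model, image) {
  desc <- embed_image(model, image)
  h <- attr(desc, "h")
  w <- attr(desc, "w")
  g <- matrix(row_norms(desc), h, w)
  rng <- range(g)
  g <- if (diff(rng) < 1e-12) matrix(0.5, h, w)
       else (g - rng[1]) / diff(rng)
  side <- model$cfg$image_size
  up <- interp_mat(side, h) %*% g %*% t(interp_mat(side, w))
  structure(clamp01(up), grid = g, class = "apnn_cam")
}

#' @export
plot.apnn_cam <- function(x, ...) {
  graphics::image(t(unclass(x))[, nrow(x):1], col = grDevices::hcl.colors(64),
                  axes = FALSE, asp = 1, ...)
  invisible(x)
}
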