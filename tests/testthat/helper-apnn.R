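# Shared fixtures, memoised for the whole test session.

.fixtures <- new.env(parent = emptyenv())

# Small on-disk synthetic dataset (built once).
tiny_dataset <- function(num_classes = 6, per_class = 6) {
  key <- sprintf("ds_%d_%d", num_classes, per_class)
  if (is.null(.fixtures[[key]])) {
    dir <- file.path(tempdir(), paste0("apnn_", key))
    .fixtures[[key]] <- build_dataset(num_classes, per_class, dir, seed = 42)
  }
  .fixtures[[key]]
}

# In-memory index with fake paths (for sampling/splitting logic only).
fake_index <- function(num_classes, per_class) {
  labels <- rep(sprintf("c%04d", seq_len(num_classes)), each = per_class)
  paths <- paste0(labels, "/", rep(seq_len(per_class), num_classes), ".png")
  dataset_index(paths, labels, check = FALSE)
}

# Exhaustive-search oracle for the image-to-class k-NN score: computes all
# m x m pairwise values with plain loops, sorts each row, sums the top /
# bottom k. Independent of the package implementation.
oracle_knn_score <- function(query, proto, k, distance) {
  m <- nrow(query)
  total <- 0
  for (i in seq_len(m)) {
    vals <- numeric(nrow(proto))
    for (j in seq_len(nrow(proto))) {
      x <- query[i, ]
      y <- proto[j, ]
      vals[j] <- switch(distance,
        cosine = {
          nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
          if (nx < 1e-12 || ny < 1e-12) 0 else sum(x * y) / (nx * ny)
        },
        euclidean = -sqrt(sum((x - y)^2)),
        manhattan = -sum(abs(x - y)))
    }
    total <- total + sum(sort(vals, decreasing = TRUE)[seq_len(k)])
  }
  total
}

rand_desc <- function(m, d) matrix(stats::rnorm(m * d), m, d)

# One desk-scale trained model shared between expensive tests (built once).
# Study conditions: 30 synthetic classes split 20/5/5 class-disjoint,
# reduced backbone with hybrid attention, 5-way 5-shot episodes.
trained_fixture <- function() {
  if (is.null(.fixtures$trained)) {
    dir <- file.path(tempdir(), "apnn_train_fixture")
    idx <- build_dataset(30, 15, dir, seed = 1)
    sp <- split_classes(idx, c(20, 5, 5), seed = 1)
    mod0 <- apnn_model("reduced", "ha", seed = 5)
    ev0 <- evaluate(mod0, sp$test, episode_spec(5, 5, 5), episodes = 60,
                    repeats = 1, seed = 9)
    cfg <- apnn_config(train_epoch = 4, train_episode = 180, ways = 5,
                       shots = 5, queries = 5, val_episode = 20, seed = 11)
    fit <- apnn(sp$train, sp$val, model = mod0, config = cfg)
    ev1 <- evaluate(fit, sp$test, episode_spec(5, 5, 5), episodes = 100,
                    repeats = 1, seed = 9)
    .fixtures$trained <- list(splits = sp, untrained = mod0, fit = fit,
                              acc_untrained = ev0$mean_accuracy,
                              acc_trained = ev1$mean_accuracy)
  }
  .fixtures$trained
}
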