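test_that("prototypes are position-wise means of their supports", {
  set.seed(1)
  one <- rand_desc(6, 4)
  p1 <- compute_prototypes(list(a = list(one)))
  expect_equal(p1$a, one)

  D <- rand_desc(6, 4)
  p0 <- compute_prototypes(list(a = list(D, -D)))
  expect_equal(p0$a, matrix(0, 6, 4))

  sets <- lapply(1:5, function(i) rand_desc(6, 4))
  pm <- compute_prototypes(list(a = sets))$a
  brute <- matrix(0, 6, 4)
  for (i in 1:6) for (j in 1:4)
    brute[i, j] <- mean(vapply(sets, function(s) s[i, j], numeric(1)))
  expect_lt(max(abs(pm - brute)), 1e-6)

  expect_error(compute_prototypes(list(a = list(rand_desc(6, 4)),
                                       b = list(rand_desc(5, 4)))), "ragged")
})

test_that("knn scores reproduce hand-worked and self-similarity cases", {
  set.seed(2)
  Q <- rand_desc(7, 5)
  expect_equal(knn_class_score(Q, Q, k = 1, distance = "cosine"), 7,
               tolerance = 1e-9)

  # two-descriptor toy: per-row best cosine matches are 1 and 1/sqrt(2)
  q <- rbind(c(1, 0), c(0, 1))
  p <- rbind(c(1, 0), c(1, 1) / sqrt(2))
  expect_equal(knn_class_score(q, p, k = 1, distance = "cosine"),
               1 + 1 / sqrt(2), tolerance = 1e-9)

  expect_warning(knn_class_score(rbind(c(0, 0), c(1, 0)), p, k = 1,
                                 distance = "cosine"), "zero-vector")
  expect_error(knn_class_score(q, p, k = 3), "k must lie")
})

test_that("knn scores equal the exhaustive-search oracle", {
  set.seed(3)
  for (i in 1:200) {
    m <- sample(2:10, 1)
    d <- sample(2:8, 1)
    k <- sample(seq_len(m), 1)
    dist <- sample(c("cosine", "euclidean", "manhattan"), 1)
    Q <- rand_desc(m, d)
    P <- rand_desc(m, d)
    expect_equal(knn_class_score(Q, P, k, dist),
                 oracle_knn_score(Q, P, k, dist), tolerance = 1e-6)
  }
})

test_that("scores are permutation invariant and maximised at the prototype", {
  set.seed(4)
  P <- rand_desc(8, 5)
  Q <- rand_desc(8, 5)
  for (dist in c("cosine", "euclidean", "manhattan")) {
    s <- knn_class_score(Q, P, 3, dist)
    expect_equal(knn_class_score(Q[sample(8), ], P[sample(8), ], 3, dist), s,
                 tolerance = 1e-9)
  }
  # replacing the query with the prototype itself never lowers the cosine score
  for (i in 1:20) {
    P <- rand_desc(6, 4)
    Q <- rand_desc(6, 4)
    expect_gte(knn_class_score(P, P, 2, "cosine"),
               knn_class_score(Q, P, 2, "cosine") - 1e-9)
  }
})

test_that("classification probabilities are a proper softmax over scores", {
  set.seed(5)
  Q <- rand_desc(5, 3)
  expect_equal(unname(classify_query(Q, list(Q))), 1.0)

  P <- rand_desc(5, 3)
  pr <- classify_query(Q, list(P, P))
  expect_equal(unname(pr), c(0.5, 0.5), tolerance = 1e-12)

  # scores (ln 2, ln 1, ln 1) -> (0.5, 0.25, 0.25)
  expect_equal(unname(apnn:::softmax(log(c(2, 1, 1)))), c(0.5, 0.25, 0.25),
               tolerance = 1e-12)

  for (i in 1:20) {
    protos <- lapply(1:4, function(j) rand_desc(5, 3))
    pr <- classify_query(rand_desc(5, 3), protos,
                         distance = sample(c("cosine", "euclidean"), 1))
    expect_equal(sum(pr), 1, tolerance = 1e-6)
    expect_true(all(pr >= 0))
  }
})

test_that("episode loss matches independent log-softmax computation", {
  set.seed(6)
  Q <- rand_desc(5, 3)
  # all-equal scores across K = 5 classes: loss = ln 5
  P <- rand_desc(5, 3)
  expect_equal(episode_loss(list(Q), replicate(5, P, simplify = FALSE), 0L),
               log(5), tolerance = 1e-9)
  # true class probability 1 gives zero loss (one dominant class)
  far <- matrix(1000, 5, 3)
  expect_equal(episode_loss(list(P), list(P, -far), 0L,
                            distance = "euclidean"), 0, tolerance = 1e-6)

  # random episode against a from-scratch oracle
  protos <- lapply(1:3, function(j) rand_desc(4, 3))
  queries <- lapply(1:6, function(j) rand_desc(4, 3))
  labels <- c(0L, 1L, 2L, 0L, 1L, 2L)
  sc <- t(vapply(queries, function(q)
    vapply(protos, function(p) oracle_knn_score(q, p, 2, "cosine"),
           numeric(1)), numeric(3)))
  nll <- -log(vapply(1:6, function(i) {
    e <- exp(sc[i, ] - max(sc[i, ]))
    (e / sum(e))[labels[i] + 1]
  }, numeric(1)))
  expect_equal(episode_loss(queries, protos, labels, k = 2), mean(nll),
               tolerance = 1e-6)
})

test_that("pairwise image similarity is bounded, 1 for identical images", {
  model <- apnn_model("reduced", "ha", seed = 7)
  bank <- generate_species_bank(2, 8)
  a <- render_image(bank[1, ], 1)
  b <- render_image(bank[2, ], 3)
  expect_equal(pair_similarity(model, a, a, k = 1), 1, tolerance = 1e-9)
  s <- pair_similarity(model, a, b)
  expect_gte(s, 0)
  expect_lte(s, 1)

  # mutually orthogonal descriptor sets score 0
  da <- cbind(diag(4), matrix(0, 4, 4))
  db <- cbind(matrix(0, 4, 4), diag(4))
  expect_equal(knn_class_score(da, db, 1, "cosine") / 4, 0)
})
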