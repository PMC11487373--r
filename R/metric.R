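# Prototype + image-to-class k-nearest-descriptor metric head.
#
# A class prototype is the position-wise mean of the support images'
# descriptor sets. A query is scored against a prototype by summing, for
# each of its m descriptors, the similarities to the k nearest prototype
# descriptors. Scores use the convention "larger = more similar": cosine
# scores are summed as-is, Euclidean/Manhattan distance sums are negated.

#' Compute class prototypes from grouped support descriptor sets
#'
#' @param support a list with one element per class, each a list of `m x d`
#'   descriptor matrices (one per support image). All sets must share the
#'   same `(m, d)` and every class the same number of supports.
#' @return a list of `m x d` prototype matrices, one per class, where
#'   prototype descriptor j is the mean of the supports' descriptor j.
#' @export
compute_prototypes <- function(support) {
  stopifnot(is.list(support), length(support) >= 1)
  dims <- unique(do.call(rbind, lapply(support, function(g)
    t(vapply(g, dim, integer(2))))))
  if (nrow(dims) != 1)
    stop("ragged descriptor sets: all must share the same (m, d)")
  ns <- vapply(support, length, integer(1))
  if (length(unique(ns)) != 1)
    stop("every class must have the same number of support sets")
  lapply(support, function(g) Reduce(`+`, g) / length(g))
}

row_norms <- function(m) sqrt(rowSums(m * m))

# Normalise rows; zero rows are left at zero (cosine similarity 0).
safe_normalize <- function(m, warn = TRUE) {
  n <- row_norms(m)
  z <- n < 1e-12
  if (any(z) && warn)
    warning("zero-vector descriptor treated as cosine similarity 0")
  n[z] <- 1
  m / n
}

# m_q x m_p matrix of pairwise similarities (larger = more similar).
pair_scores <- function(query, proto, distance, warn = TRUE) {
  switch(distance,
    cosine = safe_normalize(query, warn) %*% t(safe_normalize(proto, warn)),
    euclidean = {
      d2 <- outer(rowSums(query^2), rowSums(proto^2), `+`) -
        2 * query %*% t(proto)
      -sqrt(pmax(d2, 0))
    },
    manhattan = {
      s <- matrix(0, nrow(query), nrow(proto))
      tp <- t(proto)
      for (i in seq_len(nrow(query)))
        s[i, ] <- -colSums(abs(tp - query[i, ]))
      s
    },
    stop("unknown distance: ", distance))
}

# Per-row top-k column indices of a similarity matrix, ties broken by the
# smaller prototype index (stable) for determinism.
topk_idx <- function(S, k) {
  t(apply(S, 1, function(r) order(-r, seq_along(r))[seq_len(k)]))
}

#' Image-to-class k-nearest-descriptor score
#'
#' For each of the query's m descriptors, the k most similar prototype
#' descriptors are found and their similarities summed over all m rows.
#' With `distance = "cosine"` the score is the plain sum of cosine
#' similarities (so a query identical to the prototype scores exactly `m`
#' at `k = 1`); for `"euclidean"`/`"manhattan"` the k smallest distances
#' are summed and negated, so a larger score always means a closer match.
#'
#' @param query `m x d` query descriptor matrix.
#' @param proto `m x d` class prototype matrix.
#' @param k neighbour count (1 <= k <= m).
#' @param distance `"cosine"`, `"euclidean"` or `"manhattan"`.
#' @return a single numeric score.
#' @export
knn_class_score <- function(query, proto,
                            k = 3, distance = c("cosine", "euclidean",
                                                "manhattan")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(query), is.matrix(proto), ncol(query) == ncol(proto))
  m <- nrow(proto)
  if (k < 1 || k > m) stop("k must lie in [1, ", m, "]")
  S <- pair_scores(query, proto, distance)
  idx <- topk_idx(S, k)
  sum(S[cbind(rep(seq_len(nrow(S)), k), as.vector(idx))])
}

#' Classify a query descriptor set against class prototypes
#'
#' Produces a softmax distribution over the per-class
#' [knn_class_score()]s, with the convention that a higher score gives a
#' higher probability.
#'
#' @param query `m x d` query descriptor matrix.
#' @param prototypes list of `m x d` prototype matrices.
#' @inheritParams knn_class_score
#' @return named numeric vector of class probabilities (sums to 1).
#' @export
classify_query <- function(query, prototypes, k = 3,
                           distance = c("cosine", "euclidean", "manhattan")) {
  distance <- match.arg(distance)
  stopifnot(length(prototypes) >= 1)
  sc <- vapply(prototypes, function(p) knn_class_score(query, p, k, distance),
               numeric(1))
  p <- softmax(sc)
  names(p) <- names(prototypes) %||% seq_along(prototypes) - 1L
  p
}

#' Episodic cross-entropy loss
#'
#' Mean over queries of the negative log-probability of the true class under
#' [classify_query()]. Equals `log(K)` when all class scores tie.
#'
#' @param queries list of `m x d` query descriptor matrices.
#' @param prototypes list of `m x d` prototype matrices.
#' @param true_labels integer episode-local labels in `0..K-1`, one per
#'   query.
#' @inheritParams knn_class_score
#' @return non-negative scalar loss.
#' @export
episode_loss <- function(queries, prototypes, true_labels, k = 3,
                         distance = c("cosine", "euclidean", "manhattan")) {
  distance <- match.arg(distance)
  stopifnot(length(queries) == length(true_labels),
            all(true_labels >= 0), all(true_labels < length(prototypes)))
  nll <- vapply(seq_along(queries), function(i) {
    p <- classify_query(queries[[i]], prototypes, k, distance)
    -log(max(p[true_labels[i] + 1L], 1e-300))
  }, numeric(1))
  mean(nll)
}

#' Cosine similarity of two images under a model
#'
#' Embeds both images, treats the second as a one-image class prototype, and
#' normalises the cosine k-nearest-descriptor score to \[0, 1\] by its upper
#' bound `m * k`. Identical images score 1 (at `k = 1`); images whose
#' descriptor sets are mutually orthogonal score 0. The measure is
#' directional (A scored against B); the reverse direction can differ
#' within numerical tolerance.
#'
#' @param model an [apnn_model()] / [apnn()] object.
#' @param image_a,image_b `(side, side, 3)` image arrays.
#' @param k neighbour count (default 1, the single closest descriptor).
#' @return similarity in \[0, 1\].
#' @export
pair_similarity <- function(model, image_a, image_b, k = 1) {
  ea <- embed_image(model, image_a)
  eb <- embed_image(model, image_b)
  m <- nrow(eb)
  s <- knn_class_score(ea, eb, k = k, distance = "cosine")
  min(max(s / (m * k), 0), 1)
}
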