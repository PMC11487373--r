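test_that("squeeze dimension follows d = max(C/r, L)", {
  expect_equal(ca_squeeze_dim(64, 16, 32), 32)
  expect_equal(ca_squeeze_dim(512, 16, 32), 32)
  expect_equal(ca_squeeze_dim(1024, 16, 32), 64)
  expect_equal(ca_squeeze_dim(8, 2, 1), 4)
  expect_error(ca_squeeze_dim(0, 16, 32))
})

test_that("per-channel two-way softmax weights behave as a softmax", {
  # logits (ln 3, ln 1) -> (0.75, 0.25)
  sm <- apnn:::branch_softmax(matrix(log(3)), matrix(log(1)))
  expect_equal(sm$a[1], 0.75, tolerance = 1e-12)
  expect_equal(sm$b[1], 0.25, tolerance = 1e-12)

  set.seed(1)
  la <- matrix(rnorm(40), 8)
  lb <- matrix(rnorm(40), 8)
  sm <- apnn:::branch_softmax(la, lb)
  expect_true(all(abs(sm$a + sm$b - 1) < 1e-6))
  expect_true(all(sm$a >= 0 & sm$a <= 1))
})

test_that("tied expansion branches give equal weights and the mean map", {
  set.seed(2)
  ca <- attention_params("ca", C = 6, r = 2, L = 2, seed = 3)
  ca$par$Wb <- ca$par$Wa
  ca$par$bb <- ca$par$ba
  x <- array(rnorm(5 * 5 * 6 * 2), c(5, 5, 6, 2))
  r <- apnn:::ca_fw(ca, x, train = FALSE)
  expect_true(all(abs(r$cache$a - 0.5) < 1e-12))
  expect_equal(r$out, 0.5 * r$cache$u1 + 0.5 * r$cache$u2, tolerance = 1e-12)
})

test_that("spatial attention has the promised shape, range and symmetry", {
  sa <- attention_params("sa", seed = 4)
  # constant input: pooled maps coincide, the attention map is spatially
  # constant and the output is proportional to the input
  v <- array(2, c(6, 6, 3, 1))
  out <- spatial_attention(v, sa)
  M <- attr(out, "map")
  expect_lt(diff(range(M)), 1e-12)
  expect_equal(as.numeric(out), as.numeric(v * M[1]), tolerance = 1e-12)

  set.seed(5)
  for (i in 1:25) {
    d <- c(sample(3:9, 2), sample(1:5, 1), 1)
    x <- array(rnorm(prod(d)), d)
    out <- spatial_attention(x, sa)
    expect_equal(dim(out), d)
    M <- attr(out, "map")
    expect_true(all(M > 0 & M < 1))
  }
})

test_that("the reference embedding yields 36 descriptors of dimension 512", {
  model <- apnn_model("resnet18", "ha", seed = 1)
  img <- render_image(generate_species_bank(1, 1)[1, ], 1)
  d1 <- embed_image(model, img)
  expect_equal(dim(d1), c(36, 512))
  expect_equal(attr(d1, "h"), 6)
  expect_equal(attr(d1, "w"), 6)
  expect_true(all(is.finite(d1)))

  # evaluation-mode determinism and order-preserving batching
  img2 <- render_image(generate_species_bank(1, 1)[1, ], 2)
  batch <- embed_image(model, list(img, img2, img))
  expect_equal(batch[[1]], d1)
  expect_equal(batch[[3]], d1)
  expect_false(isTRUE(all.equal(batch[[1]], batch[[2]])))

  expect_error(embed_image(model, array(0, c(32, 32, 3))), "84")
})

test_that("all attention variants and backbones produce valid embeddings", {
  img <- render_image(generate_species_bank(1, 1)[1, ], 1)
  for (att in c("none", "ca", "sa", "ha", "cbam")) {
    model <- apnn_model("reduced", att, seed = 2)
    d <- embed_image(model, img)
    expect_equal(dim(d), c(25, 64))
  }
  d <- embed_image(apnn_model("conv64f", "none", seed = 2), img)
  expect_equal(dim(d), c(25, 64))
})

test_that("attention parameters receive gradient from an episode loss", {
  model <- apnn_model("reduced", "ha", k = 3, seed = 6)
  net <- model$net
  set.seed(10)
  x <- array(runif(84 * 84 * 3 * 6), c(84, 84, 3, 6))  # 2-way 1-shot, 2 queries each
  fw <- apnn:::net_fw(net, x, train = TRUE)
  desc <- apnn:::fmap_to_desc(fw$out)
  g <- apnn:::episode_grad(desc, ways = 2, shots = 1, labels = c(0L, 0L, 1L, 1L),
                           k = 3, distance = "cosine")
  dfm <- apnn:::desc_to_fmap(g$ddesc, model$geom$h, model$geom$w, model$geom$d)
  bw <- apnn:::net_bw(net, fw$caches, dfm)
  # the last two layers are the hybrid attention pair (ca then sa)
  n <- length(net)
  ca_g <- bw$grads[[n - 1]]
  sa_g <- bw$grads[[n]]
  for (nm in names(ca_g$par)) expect_gt(max(abs(ca_g$par[[nm]])), 0)
  expect_gt(max(abs(sa_g$par$w7)), 0)
})
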