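test_that("accuracy reproduces hand-counted T/(T+F)", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(accuracy(c(0, 1, 1, 0), c(0, 1, 0, 1)), 0.5)
  expect_equal(accuracy(c(1, 1), c(0, 0)), 0.0)
  expect_error(accuracy(integer(0), integer(0)), "positive length")
  expect_error(accuracy(1:3, 1:2), "equal")
})

test_that("a zero learning rate leaves the weights unchanged", {
  idx <- tiny_dataset(6, 6)
  model <- apnn_model("reduced", "none", k = 2, seed = 1)
  before <- apnn:::par_vec(model$net)
  cfg <- apnn_config(lr = 0, weight_decay = 0, train_epoch = 1,
                     train_episode = 2, ways = 2, shots = 1, queries = 1,
                     val_episode = 1, seed = 3)
  fit <- apnn(idx, val = NULL, model = model, config = cfg)
  expect_equal(apnn:::par_vec(fit$net), before, tolerance = 1e-15)
})

test_that("training trajectories are reproducible under a fixed seed", {
  idx <- tiny_dataset(6, 6)
  cfg <- apnn_config(train_epoch = 2, train_episode = 3, ways = 2, shots = 1,
                     queries = 1, val_episode = 2, seed = 5)
  f1 <- apnn(idx, val = NULL, model = apnn_model("reduced", "ca", seed = 2),
             config = cfg)
  f2 <- apnn(idx, val = NULL, model = apnn_model("reduced", "ca", seed = 2),
             config = cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(apnn:::par_vec(f1$net), apnn:::par_vec(f2$net))
})

test_that("every attention configuration trains without error", {
  idx <- tiny_dataset(6, 6)
  cfg <- apnn_config(train_epoch = 1, train_episode = 2, ways = 2, shots = 1,
                     queries = 1, val_episode = 1, seed = 4)
  for (att in c("none", "ca", "sa", "ha")) {
    fit <- apnn(idx, val = NULL,
                model = apnn_model("reduced", att, k = 2, seed = 2),
                config = cfg)
    expect_true(fit$trained)
    expect_true(all(is.finite(fit$history$loss)))
  }
})

test_that("an unsatisfiable episode spec fails before training starts", {
  idx <- tiny_dataset(6, 6)
  cfg <- apnn_config(train_epoch = 1, train_episode = 1, ways = 10,
                     shots = 1, queries = 1, seed = 1)
  expect_error(apnn(idx, model = apnn_model("reduced", seed = 1),
                    config = cfg), "unsatisfiable")
})

test_that("evaluation summarises oracle, degenerate and shrinking predictors", {
  idx <- fake_index(12, 6)
  spec <- episode_spec(5, 1, 3)
  oracle <- function(epi) epi$query$label
  ev <- evaluate(oracle, idx, spec, episodes = 50, repeats = 2, seed = 1)
  expect_equal(ev$mean_accuracy, 100)
  expect_equal(ev$ci_halfwidth, 0)
  expect_equal(ev$episodes_evaluated, 100)

  # constant per-episode accuracy implies zero CI half-width
  half <- function(epi) {
    lab <- epi$query$label
    ifelse(seq_along(lab) %% 3 == 0, -1L, lab)  # always 10 of 15 correct
  }
  ev2 <- evaluate(half, idx, spec, episodes = 40, repeats = 1, seed = 2)
  expect_equal(ev2$ci_halfwidth, 0)

  # CI shrinks like 1/sqrt(episodes) for a fixed stochastic predictor
  rnd <- function(epi) sample(0:4, nrow(epi$query), replace = TRUE)
  e100 <- evaluate(rnd, idx, spec, episodes = 100, repeats = 1, seed = 3)
  e400 <- evaluate(rnd, idx, spec, episodes = 400, repeats = 1, seed = 3)
  ratio <- e100$ci_halfwidth / e400$ci_halfwidth
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.9)

  expect_error(evaluate(oracle, fake_index(3, 4), spec), "too few classes")
})

test_that("activation maps are bounded, grid-sized and degenerate-safe", {
  model <- apnn_model("reduced", "none", seed = 3)
  bank <- generate_species_bank(3, 5)
  for (i in 1:5) {
    cam <- activation_map(model, render_image(bank[(i %% 3) + 1, ], i))
    expect_equal(dim(unclass(cam)), c(84, 84))
    expect_true(all(cam >= 0 & cam <= 1))
    expect_equal(dim(attr(cam, "grid")), c(5, 5))
  }
  # resnet18 geometry: 6x6 grid before upsampling
  cam18 <- activation_map(apnn_model("resnet18", "none", seed = 1),
                          render_image(bank[1, ], 1))
  expect_equal(dim(attr(cam18, "grid")), c(6, 6))

  # constant features (zeroed final stage) give the all-0.5 guard value
  degen <- model
  # zero the last convolution so descriptors are constant across positions
  for (i in seq_along(degen$net)) {
    if (degen$net[[i]]$type == "conv") ilast <- i
  }
  degen$net[[ilast]]$par$w[] <- 0
  degen$net[[ilast]]$par$b[] <- 0
  camd <- activation_map(degen, render_image(bank[1, ], 1))
  expect_true(all(abs(attr(camd, "grid") - 0.5) < 1e-12))
})

test_that("model methods print, summarise, predict and plot coherently", {
  idx <- tiny_dataset(6, 6)
  model <- apnn_model("reduced", "ha", seed = 1)
  expect_output(print(model), "untrained")
  expect_output(print(summary(model)), "Descriptor geometry")
  expect_error(plot(model), "no training history")
  expect_length(coef(model), length(model$net))

  epi <- sample_episode(idx, episode_spec(3, 2, 2), seed = 1)
  pred <- predict(model, epi)
  expect_length(pred, 6)
  expect_true(all(pred %in% 0:2))
  pr <- predict(model, epi, type = "prob")
  expect_equal(dim(pr), c(6, 3))
  expect_equal(unname(rowSums(pr)), rep(1, 6), tolerance = 1e-9)

  cfg <- apnn_config(train_epoch = 1, train_episode = 2, ways = 2, shots = 1,
                     queries = 1, val_episode = 1, seed = 2)
  fit <- apnn(idx, val = NULL, model = model, config = cfg)
  expect_output(print(fit), "trained: 1 epochs")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
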