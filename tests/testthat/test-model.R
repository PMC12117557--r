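# Hybrid model: loss closed forms, the concatenation contract, training
# behavior, determinism and checkpointing.

test_that("binary cross-entropy matches its closed form", {
  expect_equal(bce_loss(rep(0.5, 7), c(1, 0, 1, 1, 0, 0, 1)), log(2),
               tolerance = 1e-9)
  expect_equal(bce_loss(c(0.9, 0.1), c(1, 0)), -log(0.9), tolerance = 1e-9)
  # perfect prediction collapses to the clipping floor
  expect_equal(bce_loss(c(1, 0), c(1, 0)), -log(1 - 1e-7), tolerance = 1e-12)
  expect_gte(bce_loss(runif(5), rbinom(5, 1, 0.5)), 0)
  expect_error(bce_loss(c(0.5, 0.5), 1), "length")
})

test_that("the MLP head concatenates h then h_dp at the declared width", {
  # learned representation of 128 + 391 descriptors -> input width 519
  set.seed(50)
  params <- vshybrid:::mlp_init_params(519, c(128L, 64L))
  expect_equal(nrow(params[["mlp.W1"]]), 519)
  p <- predict_one(h = rnorm(128), h_dp = rnorm(391), params = params)
  expect_true(p > 0 && p < 1)
  expect_error(predict_one(h = rnorm(128), h_dp = rnorm(10), params = params),
               "width")
  # descriptor-only mode reduces to an MLP on h_dp alone
  params2 <- vshybrid:::mlp_init_params(23, c(16L))
  p2 <- predict_one(h_dp = rnorm(23), params = params2, hidden = 16L)
  expect_true(p2 > 0 && p2 < 1)
  # all-zero weights and bias give sigmoid(0) = 0.5 for any input
  zero <- lapply(params, function(x) x * 0)
  expect_equal(predict_one(h = rnorm(128), h_dp = rnorm(391), params = zero),
               0.5)
  # concatenation order is [h then h_dp] (single hidden layer probe)
  probe <- lapply(vshybrid:::mlp_init_params(519, 4L), function(x) x * 0)
  probe[["mlp.W1"]][1, 1] <- 1          # reads the first component of h
  probe[["mlp.W1"]][129, 2] <- 1        # reads the first component of h_dp
  probe[["mlp.Wout"]][1, 1] <- 1
  h <- c(5, rep(0, 127)); hdp <- c(-3, rep(0, 390))
  expect_equal(predict_one(h, hdp, probe, hidden = 4L), plogis(5))  # relu kills -3
  probe[["mlp.Wout"]][1, 1] <- 0; probe[["mlp.Wout"]][2, 1] <- 1
  expect_equal(predict_one(h, -hdp, probe, hidden = 4L), plogis(3))
})

test_that("training is reproducible, loss-decreasing and epoch-exact", {
  # linearly separable toy problem on a single descriptor feature
  set.seed(51)
  x <- matrix(c(rnorm(40, -2), rnorm(40, 2)), ncol = 1)
  colnames(x) <- "f"
  y <- rep(c(0, 1), each = 40)
  cfg <- hybrid_config(encoder = NULL, mlp_hidden = c(8L), dropout = 0,
                       epochs = 40, batch_size = 16, seed = 4)
  m <- train_hybrid(y, cfg, descriptors = x)
  expect_length(m$history, 40)
  expect_lt(m$history[40], m$history[1])
  r <- score_test_set(m, descriptors = x)
  expect_gt(min(r$score[y == 1]), max(r$score[y == 0]) - 0.2)

  m2 <- train_hybrid(y, cfg, descriptors = x)
  expect_identical(m$history, m2$history)     # bit-identical under one seed
  expect_identical(m$params, m2$params)

  cfg1 <- hybrid_config(encoder = NULL, mlp_hidden = c(8L), epochs = 1, seed = 4)
  m3 <- train_hybrid(y, cfg1, descriptors = x)
  expect_length(m3$history, 1)

  expect_error(train_hybrid(rep(1, 10), cfg, descriptors = x[1:10, , drop = FALSE]),
               "both classes")
})

test_that("a model trained without descriptors ignores descriptor input", {
  sd1 <- fixture_synth(120, 0.1, seed = 21)
  graphs <- featurize_set(sd1$set)
  desc <- molecule_descriptors(sd1$set)
  cfg <- hybrid_config(encoder = encoder_config("gcn", hidden = 16, layers = 2),
                       use_descriptors = FALSE, mlp_hidden = c(16L),
                       epochs = 3, seed = 8)
  m <- train_hybrid(activities(sd1$set), cfg, graphs = graphs)
  r1 <- score_test_set(m, graphs)
  r2 <- score_test_set(m, graphs, descriptors = desc * 100)
  expect_identical(r1$score, r2$score)
})

test_that("scoring is deterministic and separates a memorized training set", {
  sd1 <- fixture_synth(120, 0.1, seed = 21)
  graphs <- featurize_set(sd1$set)
  desc <- molecule_descriptors(sd1$set)
  y <- activities(sd1$set)
  cfg <- hybrid_config(encoder = encoder_config("gcn", hidden = 32),
                       mlp_hidden = c(32L), epochs = 20, seed = 12)
  m <- train_hybrid(y, cfg, graphs = graphs, descriptors = desc)
  r <- score_test_set(m, graphs, desc)
  # same molecule scored twice gets the same score
  rdup <- score_test_set(m, graphs[c(1, 1, 2)],
                         desc[c(1, 1, 2), , drop = FALSE])
  expect_equal(rdup$score[1], rdup$score[2])
  # training-set AUC above chance for a memorizing model
  auc <- mean(outer(r$score[y == 1], r$score[y == 0], ">") +
                0.5 * outer(r$score[y == 1], r$score[y == 0], "=="))
  expect_gt(auc, 0.5)
  # descriptor width mismatch against the fitted scaler is fatal
  expect_error(score_test_set(m, graphs, desc[, 1:5]), "does not match")
})

test_that("checkpoints round-trip parameters, config and scaler", {
  sd1 <- fixture_synth(120, 0.1, seed = 21)
  graphs <- featurize_set(sd1$set)
  desc <- molecule_descriptors(sd1$set)
  cfg <- hybrid_config(encoder = encoder_config("gcn", hidden = 8, layers = 1),
                       mlp_hidden = c(8L), epochs = 2, seed = 3)
  m <- train_hybrid(activities(sd1$set), cfg, graphs = graphs, descriptors = desc)
  f <- tempfile(fileext = ".json")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_equal(m2$history, m$history)
  r1 <- score_test_set(m, graphs, desc)
  r2 <- score_test_set(m2, graphs, desc)
  expect_equal(r2$score, r1$score, tolerance = 1e-12)
})
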