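make_tiny_pairs <- function(n_cases = 3, seed = 50) {
  pairs <- list()
  for (i in seq_len(n_cases)) {
    ph <- generate_phantom(tiny_spec(seed = seed + i))
    pl <- build_pairs(ph$series, sprintf("case%d", i))[c(1, 10, 20, 30, 45)]
    pairs <- c(pairs, lapply(pl, standardize_pair))
  }
  pairs
}

test_that("gradients of every architecture match numeric differentiation", {
  set.seed(60)
  x <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 1, 2))
  y <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 1, 2))
  models <- list(tiny_dncnn(units = 2L), tiny_win5rb(kernel = 3L),
                 tiny_resunet(c(3L, 4L)))
  for (model in models) {
    model <- randomize_final_conv(model, seed = 61)
    fw <- model_forward(model, x, training = TRUE)
    g <- model_backward(model, fw$cache, 2 * (fw$out - y) / length(fw$out))
    loss_at <- function(m) {
      mean((model_forward(m, x, training = TRUE)$out - y)^2)
    }
    set.seed(62)
    for (nm in sample(names(model$params), 6)) {
      i <- sample(length(model$params[[nm]]), 1)
      h <- 1e-5
      mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
      mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
      gn <- (loss_at(mp) - loss_at(mm)) / (2 * h)
      expect_equal(g[[nm]][i], gn, tolerance = 1e-3)
    }
  }
})

test_that("a short run reduces the training loss", {
  pairs <- make_tiny_pairs()
  cfg <- train_config(learning_rate = 2e-3, max_epochs = 3L, batch_size = 4L,
                      seed = 1L)
  res <- train(tiny_dncnn(), pairs[1:10], pairs[11:15], cfg)
  expect_lt(res$history$train_loss[3], res$history$train_loss[1])
  expect_equal(nrow(res$history), 3L)
})

test_that("the returned model is the minimum-validation-loss checkpoint", {
  pairs <- make_tiny_pairs(seed = 70)
  cfg <- train_config(learning_rate = 5e-3, max_epochs = 4L, batch_size = 4L,
                      seed = 2L)
  res <- train(tiny_win5rb(kernel = 3L), pairs[1:10], pairs[11:15], cfg)
  h <- res$history
  expect_equal(attr(h, "best_val_loss"), min(h$val_loss))
  expect_equal(h$val_loss[attr(h, "best_epoch")], min(h$val_loss))
  # re-evaluating the returned weights reproduces the best validation loss
  va <- fastdmsa:::pairs_to_tensors(pairs[11:15])
  expect_equal(fastdmsa:::eval_loss(res$model, va$X, va$Y, 4L),
               attr(h, "best_val_loss"), tolerance = 1e-12)
})

test_that("training is reproducible for a fixed seed", {
  pairs <- make_tiny_pairs(seed = 80)
  cfg <- train_config(learning_rate = 2e-3, max_epochs = 2L, batch_size = 4L,
                      seed = 3L)
  r1 <- train(tiny_dncnn(), pairs[1:8], pairs[9:12], cfg)
  r2 <- train(tiny_dncnn(), pairs[1:8], pairs[9:12], cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
  expect_error(train(tiny_dncnn(), list(), pairs[1:2], cfg), "non-empty")
})

test_that("prediction path standardizes, clips at zero, and passes identity", {
  ph <- generate_phantom(tiny_spec(seed = 90L))
  short <- sum_frames(ph$series, c(1, 2))
  m <- tiny_dncnn()   # untrained: identity mapping
  pred <- predict_counts(m, short)
  expect_equal(pred, short, tolerance = 1e-10)
  expect_true(all(predict_counts(randomize_final_conv(m, sd = 5), short) >= 0))
})

test_that("an overfit tiny model approaches a noise-free scaled target", {
  ph <- generate_phantom(tiny_spec(seed = 91L))
  target <- sum_frames(ph$series)
  input <- target / 5   # exact noise-free 1:5 scaling
  st <- standardize(input)
  pair <- list(case_id = "c", frame_indices = c(1L, 2L), short_time = input,
               full_time = target, input_std = st$image,
               target_std = (target - st$params$mean) / st$params$sd,
               params = st$params)
  cfg <- train_config(learning_rate = 5e-2, max_epochs = 100L, batch_size = 1L,
                      seed = 4L)
  res <- train(tiny_dncnn(units = 1L), list(pair), list(pair), cfg)
  pred <- predict_counts(res$model, input, st$params)
  expect_lt(nmse(pred, target), nmse(input, target) / 10)
})
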